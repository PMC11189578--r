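test_that("hampel filter matches hand-computed examples and edge rules", {
  # median 3, MAD 1, bounds [0, 6]: 100 is dropped
  expect_equal(hampel_filter(c(1, 2, 3, 4, 100)), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # zero spread: all at the median, all kept (with the MAD = 0 warning)
  expect_warning(keep <- hampel_filter(c(5, 5, 5, 5)), "median absolute deviation")
  expect_true(all(keep))
  # MAD = 0 with a deviant value: only the median survives
  expect_warning(keep2 <- hampel_filter(c(5, 5, 5, 9)), "median")
  expect_equal(keep2, c(TRUE, TRUE, TRUE, FALSE))
  # groups smaller than 3 pass untouched
  expect_equal(hampel_filter(7), TRUE)
  expect_equal(hampel_filter(c(1, 100)), c(TRUE, TRUE))
})

test_that("hampel filter always catches gross outliers and is monotone in k", {
  # (strict idempotence cannot hold for arbitrary continuous samples: removing
  # points re-shrinks the MAD, so a second pass may flag borderline values)
  set.seed(42)
  for (i in 1:25) {
    x <- c(rnorm(sample(6:20, 1), sd = 0.5), 50)
    k3 <- suppressWarnings(hampel_filter(x, k = 3))
    expect_false(k3[length(x)], info = paste("iteration", i))
    # widening the band can only keep more values
    k6 <- suppressWarnings(hampel_filter(x, k = 6))
    expect_true(all(k6[k3]), info = paste("iteration", i))
  }
})

test_that("fecundity, seed mass and stress response derivations are exact", {
  expect_equal(derive_fecundity(100, 12), 1200)
  expect_equal(derive_fecundity(0, NA), 0)
  expect_equal(derive_fecundity(37, 9.5), 351.5)
  expect_warning(out <- derive_fecundity(c(10, 5), c(NA, 8)), "no usable fruit length")
  expect_equal(out, c(NA, 40))

  expect_equal(derive_seed_mass(0.60, 30), 0.02)
  expect_error(derive_seed_mass(0.5, 0), "positive")
  expect_warning(derive_seed_mass(0.5, 5), "10-30")
  expect_equal(mean(c(derive_seed_mass(0.4, 20), derive_seed_mass(0.48, 20))), 0.022)

  expect_equal(as.numeric(stress_response(400, 1200)), -800)
  expect_equal(as.numeric(stress_response(400, 400)), 0)
  expect_equal(as.numeric(stress_response(400 + 1e-6, 400)), 1e-6)
  expect_equal(as.numeric(stress_response(400, 1200, mode = "magnitude")), 800)
  expect_equal(attr(stress_response(1, 2, mode = "magnitude"), "response_mode"), "magnitude")
})

test_that("biogeographical classification applies the 45/55 and 50% rules", {
  expect_equal(as.character(classify_biogeo(40, 0.8)), "South relict")
  expect_equal(as.character(classify_biogeo(50, 0.1)), "Center cosmopolitan")
  expect_equal(as.character(classify_biogeo(60, 0.6)), "North relict")
  expect_equal(as.character(classify_biogeo(44.9, 0.5)), "South cosmopolitan") # 0.5 is not > 0.5
  # threshold ties go to the center, with a warning
  expect_warning(lab <- classify_biogeo(45, 0.2), "threshold")
  expect_equal(as.character(lab), "Center cosmopolitan")
  # center + relict is rejected unless permissive
  expect_error(classify_biogeo(50, 0.9), "Center relict")
  expect_equal(as.character(classify_biogeo(50, 0.9, permissive = TRUE)), "Center relict")
  # total and deterministic over a grid; exactly five labels
  grid <- expand.grid(lat = c(30, 44, 46, 54, 56, 70), anc = c(0, 0.3, 0.51, 1))
  labs <- classify_biogeo(grid$lat, grid$anc, permissive = TRUE)
  expect_false(anyNA(labs))
  expect_true(all(levels(classify_biogeo(40, 0.8)) == c(
    "North relict", "North cosmopolitan", "Center cosmopolitan",
    "South cosmopolitan", "South relict"
  )))
})

test_that("method-of-moments heritability behaves at its limits", {
  df <- data.frame(g = rep(letters[1:4], each = 4), y = rep(c(1, 5, 9, 13), each = 4))
  expect_equal(heritability(df, y, g)$H2, 1)
  # shuffling genotype labels destroys heritability
  set.seed(7)
  d <- data.frame(
    g = rep(sprintf("g%02d", 1:30), each = 6),
    y = rep(rnorm(30, sd = 2), each = 6) + rnorm(180)
  )
  h_true <- heritability(d, y, g)$H2
  h_null <- mean(vapply(1:100, function(i) {
    d2 <- d
    d2$g <- sample(d2$g)
    heritability(d2, y, g)$H2
  }, numeric(1)))
  expect_gt(h_true, 0.5)
  expect_lt(h_null, 0.1)
  # single replicate throughout: residual variance inestimable
  expect_error(
    heritability(data.frame(g = c("a", "b", "c"), y = 1:3), y, g),
    "replication"
  )
})

test_that("label-shuffling null test is calibrated and hits its floor under separation", {
  set.seed(11)
  n <- 40
  labels <- sample(rep(c("A", "B", "C", "D"), each = 10))
  # calibration: exchangeable data give approximately uniform p (KS at alpha = 0.01)
  ps <- vapply(1:150, function(i) {
    d <- data.frame(group = labels, y = rnorm(n))
    null_group_test(d, "y", n_reps = 100, seed = i)$p[1]
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  # extreme separation: p at the add-one floor
  d <- data.frame(group = labels, y = rnorm(n))
  d$y[d$group == "A"] <- d$y[d$group == "A"] + 5 * sd(d$y)
  res <- null_group_test(d, "y", n_reps = 100, seed = 1)
  expect_equal(res$p[res$group == "A"], 1 / 101)
  # n_reps = 1: only two possible p values
  r1 <- null_group_test(d, "y", n_reps = 1, seed = 2)
  expect_true(all(r1$p %in% c(0.5, 1)))
})

test_that("trait correlations recover exact and generated structure", {
  d <- data.frame(x = c(1, 2, 3, 5, 8), y = -c(1, 2, 3, 5, 8), z = c(2, 1, 7, 4, 3))
  res <- trait_correlations(d, c("x", "y", "z"))
  m <- attr(res, "matrix")
  expect_equal(unname(diag(m)), c(1, 1, 1))
  expect_equal(m["x", "y"], -1)
  expect_equal(m, t(m))
  expect_warning(trait_correlations(data.frame(a = rep(1, 5), b = 1:5), c("a", "b")), "zero-variance")
  # generated trade-off: negative fecundity/seed-mass correlation at the genotype level
  fb <- demo_fixture()
  tr <- genotype_traits(fb$plants, fb$metadata)
  r_fs <- attr(
    trait_correlations(tr, c("fecundity_control", "seed_mass")),
    "matrix"
  )["fecundity_control", "seed_mass"]
  expect_lt(r_fs, 0)
})

test_that("genotype trait derivation keeps exact record accounting and the response identity", {
  cfg <- sim_config(
    n_snps = 150, n_windows = 30, attrition_rate = 0.08,
    neighbor_loss_rate = 0.25, outlier_rate = 0.03, seed = 13
  )
  fb <- simulate_study(cfg)
  tr <- genotype_traits(fb$plants, fb$metadata)
  audit <- attr(tr, "audit")
  expect_equal(
    audit$n_input,
    audit$n_incomplete + audit$n_no_neighbors + audit$n_hampel + audit$n_kept
  )
  expect_equal(sum(audit$n_input), nrow(fb$plants))
  expect_gt(sum(audit$n_no_neighbors), 0)
  expect_gt(sum(audit$n_incomplete), 0)
  # signed-mode response identity is exact
  expect_equal(
    tr$response_competition,
    tr$fecundity_competition - tr$fecundity_control
  )
  expect_equal(attr(tr, "response_mode"), "signed")
  # magnitude mode flips nothing but signs
  tr2 <- genotype_traits(fb$plants, fb$metadata, response_mode = "magnitude")
  expect_equal(tr2$response_competition, abs(tr$response_competition))
})

test_that("clean data stays at the small-sample Hampel baseline; gross outliers are caught", {
  cfg0 <- sim_config(n_snps = 150, n_windows = 30, outlier_rate = 0, seed = 21)
  fb0 <- simulate_study(cfg0)
  tr0 <- genotype_traits(fb0$plants, fb0$metadata)
  a0 <- attr(tr0, "audit")
  baseline <- sum(a0$n_hampel) / sum(a0$n_input)
  # raw-MAD rule at 8 replicates flags a few percent of clean continuous data
  expect_lt(baseline, 0.35)
  # injected gross outliers (8x fruit counts) are removed at a far higher rate
  cfg1 <- sim_config(n_snps = 150, n_windows = 30, outlier_rate = 0.05, seed = 21)
  fb1 <- simulate_study(cfg1)
  tr1 <- genotype_traits(fb1$plants, fb1$metadata)
  a1 <- attr(tr1, "audit")
  expect_gt(sum(a1$n_hampel) / sum(a1$n_input), baseline + 0.02)
})
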