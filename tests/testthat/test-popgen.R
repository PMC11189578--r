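test_that("MAF filter applies the strict cutoff and matches a brute-force recount", {
  x <- rbind(
    rep(c(0L, 1L), c(19, 1)), # freq 1/20 = 0.05 at SNP level after transpose
    rep(0L, 20), rep(1L, 20)
  )
  # build per-SNP: 20 genotypes x 3 SNPs with freqs 0.05, 0, 1
  g <- genotype_matrix(
    t(x),
    tibble::tibble(
      snp_id = c("at_cutoff", "mono0", "mono1"), chrom = "1",
      pos = c(0L, 10L, 20L), coding = TRUE
    )
  )
  expect_error(maf_filter(g), "removed all")
  g2 <- random_genotype_matrix(30, 200, missing = 0.05, seed = 2)
  kept <- maf_filter(g2, 0.1)
  # independent recount
  p <- colMeans(g2$dosage, na.rm = TRUE)
  expect_equal(n_snps(kept), sum(pmin(p, 1 - p) > 0.1))
  expect_setequal(kept$snps$snp_id, g2$snps$snp_id[pmin(p, 1 - p) > 0.1])
})

test_that("LD pruning drops correlated later SNPs, keeps independent ones, rejects unsorted maps", {
  set.seed(3)
  base <- rbinom(60, 1L, 0.5)
  x <- cbind(base, base, 1L - base, rbinom(60, 1L, 0.5))
  g <- genotype_matrix(x, tibble::tibble(
    snp_id = paste0("s", 1:4), chrom = "1",
    pos = c(0L, 1000L, 2000L, 3000L), coding = TRUE
  ))
  kept <- ld_prune(g, r2_max = 0.1)
  expect_equal(kept, c("s1", "s4")) # duplicates and the inverted copy dropped
  # mutually independent SNPs all survive a loose threshold
  g2 <- random_genotype_matrix(200, 30, seed = 4, span_bp = 40000L)
  expect_equal(length(ld_prune(g2, r2_max = 0.5)), 30L)
  # unsorted positions error rather than silently sorting
  bad <- genotype_matrix(x, tibble::tibble(
    snp_id = paste0("s", 1:4), chrom = "1",
    pos = c(1000L, 0L, 2000L, 3000L), coding = TRUE
  ))
  expect_error(ld_prune(bad), "sorted")
})

test_that("LD pruning agrees with the exhaustive-pairs oracle on one-window instances", {
  for (i in 1:10) {
    g <- random_genotype_matrix(30, 20, missing = 0.02, seed = 100 + i, span_bp = 40000L)
    kept <- ld_prune(g, r2_max = 0.3, window_bp = 50000, step_snps = 50)
    oracle <- oracle_ld_prune_one_window(g$dosage, r2_max = 0.3)
    expect_equal(kept, g$snps$snp_id[oracle], info = paste("instance", i))
  }
})

test_that("Weir-Cockerham F_ST hits its analytic limits", {
  # identical frequencies in both groups: theta near 0
  set.seed(5)
  x <- matrix(rbinom(200 * 50, 1L, 0.4), 200, 50)
  g <- genotype_matrix(x, tibble::tibble(
    snp_id = sprintf("s%02d", 1:50), chrom = "1", pos = seq(0L, 490L, 10L),
    coding = TRUE
  ))
  grp <- stats::setNames(rep(c("a", "b"), each = 100), genotype_ids(g))
  f <- wc_fst(g, grp)
  expect_lt(abs(attr(f, "fst_overall")), 0.02)
  # fixed difference: theta = 1
  x2 <- rbind(matrix(0L, 5, 3), matrix(1L, 5, 3))
  g2 <- genotype_matrix(x2, tibble::tibble(
    snp_id = c("f1", "f2", "f3"), chrom = "1", pos = c(0L, 10L, 20L), coding = TRUE
  ))
  f2 <- wc_fst(g2, stats::setNames(rep(c("a", "b"), each = 5), genotype_ids(g2)))
  expect_equal(f2$fst, rep(1, 3))
  # monomorphic SNP undefined and excluded from the ratio-of-sums
  x3 <- cbind(x2[, 1], rep(1L, 10))
  g3 <- genotype_matrix(x3, tibble::tibble(
    snp_id = c("poly", "mono"), chrom = "1", pos = c(0L, 10L), coding = TRUE
  ))
  f3 <- wc_fst(g3, stats::setNames(rep(c("a", "b"), each = 5), genotype_ids(g3)))
  expect_true(is.na(f3$fst[2]))
  expect_equal(attr(f3, "fst_overall"), 1)
  # too-small groups rejected
  expect_error(
    wc_fst(g2, stats::setNames(rep(c("a", "b"), c(1, 9)), genotype_ids(g2))),
    ">= 2"
  )
})

test_that("F_ST equals the independent variance-components oracle on exhaustive small instances", {
  set.seed(6)
  for (i in 1:60) {
    n_geno <- sample(4:10, 1)
    n_snp <- sample(2:10, 1)
    n_grp <- sample(2:3, 1)
    g <- random_genotype_matrix(n_geno, n_snp,
      missing = sample(c(0, 0.15), 1),
      seed = 1000 + i
    )
    grp <- rep(letters[seq_len(n_grp)], length.out = n_geno)
    sizes <- table(grp)
    if (any(sizes < 2)) grp <- rep(letters[1:2], length.out = n_geno)
    grp <- stats::setNames(grp, genotype_ids(g))
    f <- wc_fst(g, grp)
    orc <- oracle_wc_fst(g$dosage, grp)
    expect_equal(f$a, orc$a, tolerance = 1e-10, info = paste("instance", i))
    expect_equal(f$c, orc$c, tolerance = 1e-10, info = paste("instance", i))
    expect_equal(f$fst, orc$fst, tolerance = 1e-10, info = paste("instance", i))
  }
})

test_that("ratio-of-sums F_ST is invariant to SNP reordering and within-group relabeling", {
  g <- random_genotype_matrix(20, 40, seed = 7)
  grp <- stats::setNames(rep(c("a", "b"), each = 10), genotype_ids(g))
  f <- wc_fst(g, grp)
  perm <- sample(n_snps(g))
  g_perm <- genotype_matrix(g$dosage[, perm], g$snps[perm, ])
  f_perm <- wc_fst(g_perm, grp)
  expect_equal(attr(f, "fst_overall"), attr(f_perm, "fst_overall"))
  rows <- c(sample(1:10), sample(11:20))
  g_rows <- genotype_matrix(g$dosage[rows, ], g$snps)
  f_rows <- wc_fst(g_rows, grp)
  expect_equal(attr(f, "fst_overall"), attr(f_rows, "fst_overall"))
})

test_that("Q_ST limits, affine invariance and the mating-system denominator", {
  grp <- rep(c("a", "b", "c"), each = 4)
  set.seed(8)
  within <- rnorm(12)
  # identical group means with within spread: Q_ST = 0 (moment estimate truncates)
  v0 <- within - stats::ave(within, grp) + 5
  expect_equal(qst(v0, grp)$qst, 0)
  # zero within variance with differing means: Q_ST = 1
  v1 <- rep(c(1, 5, 9), each = 4)
  expect_equal(qst(v1, grp)$qst, 1)
  # affine rescaling leaves Q_ST unchanged
  v <- within + rep(c(0, 2, 4), each = 4)
  expect_equal(qst(v, grp)$qst, qst(100 + 42 * v, grp)$qst)
  # outcrossing denominator halves the within contribution's weight
  r <- qst(v, grp)
  r2 <- qst(v, grp, mode = "outcrossing")
  expect_equal(r2$qst, r$sigma2_B / (r$sigma2_B + 2 * r$sigma2_W))
  expect_error(qst(v, rep("a", 12)), "groups")
})

test_that("Q_ST-in-F_ST bootstrap ranks and floors correctly", {
  grp <- rep(c("a", "b"), each = 6)
  set.seed(9)
  # weakly differentiated trait vs a high-F_ST genome
  v_low <- rnorm(12, sd = 1) + rep(c(0, 0.1), each = 6)
  fst_high <- runif(500, 0.3, 0.9)
  t_low <- qst_fst_test(v_low, grp, fst_high, n_boot = 300, seed = 1)
  expect_lt(t_low$quantile, 0.5)
  expect_gt(t_low$p, 0.1)
  # trait above the genome-wide maximum F_ST: p at the add-one floor
  v_hi <- rep(c(0, 10), each = 6) + rnorm(12, sd = 0.01)
  fst_low <- runif(400, 0, 0.3)
  t_hi <- qst_fst_test(v_hi, grp, fst_low, n_boot = 300, seed = 2)
  expect_equal(t_hi$p, 1 / 301)
  expect_equal(t_hi$quantile, 1)
  expect_warning(qst_fst_test(v_hi, grp, fst_low, n_boot = 50, seed = 3), "coarse")
})

test_that("coancestry estimates relatedness structure and applies the completeness rule", {
  set.seed(10)
  # two independent panmictic clusters
  p1 <- runif(300, 0.1, 0.9)
  p2 <- runif(300, 0.1, 0.9)
  x <- rbind(
    t(replicate(10, rbinom(300, 1L, p1))),
    t(replicate(10, rbinom(300, 1L, p2)))
  )
  x <- rbind(x, x[1, ]) # duplicated genotype
  rownames(x) <- sprintf("g%02d", 1:21)
  g <- genotype_matrix(x, tibble::tibble(
    snp_id = sprintf("s%03d", 1:300), chrom = "1", pos = seq_len(300) * 10L,
    coding = FALSE
  ))
  th <- coancestry_mom(g)
  expect_true(isSymmetric(unclass(th)))
  expect_true(all(eigen(unclass(th), symmetric = TRUE, only.values = TRUE)$values > -1e-8))
  # duplicate pair coancestry matches self-coancestry
  expect_lt(abs(th["g01", "g21"] - (th["g01", "g01"] + th["g21", "g21"]) / 2), 0.05)
  within <- th[2:10, 2:10][lower.tri(matrix(0, 9, 9))]
  between <- th[2:10, 11:20]
  expect_gt(mean(within), mean(between))
  # completeness rule: a SNP with 6% missing genotypes is excluded at 5%
  x2 <- x
  x2[1:2, 1] <- NA # 2/21 = 9.5% missing at SNP 1
  g2 <- genotype_matrix(x2, g$snps)
  expect_equal(attr(coancestry_mom(g2), "n_snps"), attr(th, "n_snps") - 1L)
  expect_error(coancestry_mom(subset_snps(g, sprintf("s%03d", 1:40))), ">= 50")
})

test_that("S statistic reaches its three limiting regimes", {
  theta <- matrix(0.05, 5, 5)
  diag(theta) <- 0.25
  rownames(theta) <- colnames(theta) <- paste0("grp", 1:5)
  G <- matrix(c(1, -0.5, -0.5, 1), 2, dimnames = list(c("t1", "t2"), c("t1", "t2")))
  # stabilizing limit: all group means identical
  m0 <- matrix(5, 5, 2, dimnames = dimnames_like <- list(rownames(theta), colnames(G)))
  s0 <- s_statistic(m0, theta, G, n_draws = 300, seed = 1)
  expect_equal(s0$S, 0)
  # directional limit: +-10 within-group SD along the trade-off axis
  disp <- 10 * outer(c(1, -1, 1, -1, 1), c(1, -1) / sqrt(2))
  m1 <- m0 + disp
  s1 <- s_statistic(m1, theta, G, n_draws = 300, seed = 2)
  expect_gte(s1$S, 0.95)
  # drift regime: means drawn under the neutral model give S near 0.5
  ch_s <- chol(2 * theta)
  ch_g <- chol(G)
  set.seed(3)
  svals <- vapply(1:30, function(i) {
    z <- matrix(rnorm(10), 5, 2)
    m <- matrix(5, 5, 2, dimnames = dimnames_like) + t(ch_s) %*% z %*% ch_g
    s_statistic(m, theta, G, n_draws = 400)$S
  }, numeric(1))
  expect_gt(mean(svals), 0.35)
  expect_lt(mean(svals), 0.65)
})

test_that("group trait means and pooled covariance align with direct computation", {
  fb <- demo_fixture()
  tr <- genotype_traits(fb$plants, fb$metadata)
  vars <- c("fecundity_control", "seed_mass")
  gm <- group_trait_means(tr, vars)
  expect_equal(
    gm["South relict", "seed_mass"],
    mean(tr$seed_mass[tr$group == "South relict"])
  )
  G <- within_group_cov(tr, vars)
  expect_true(isSymmetric(G))
  expect_true(all(diag(G) > 0))
})
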