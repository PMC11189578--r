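mk_fst_tbl <- function(ids, fst, pair = "A vs B") {
  tibble::tibble(
    snp_id = ids, chrom = "1", pos = seq_along(ids) * 10L, pair = pair,
    a = fst, b = 0, c = 1 - fst, fst = fst
  )
}

test_that("F_STQ ratio arithmetic and the exchangeability null behave", {
  nc_ids <- sprintf("nc%03d", 1:200)
  top_ids <- sprintf("top%02d", 1:20)
  # top SNPs all fixed differences, neutral mean 0.2: ratio exactly 5
  f <- mk_fst_tbl(c(top_ids, nc_ids), c(rep(1, 20), rep(0.2, 200)))
  r <- fstq_ratio(f, top_ids, nc_ids)
  expect_equal(r$ratio, 5)
  expect_equal(r$fstq, 1)
  expect_equal(r$fst_neutral, 0.2)
  expect_lt(r$p, 1e-6)
  # top sets drawn from the neutral pool: ratio near 1, mostly non-significant
  set.seed(15)
  fst_vals <- rbeta(600, 0.8, 4)
  all_ids <- sprintf("s%03d", 1:600)
  f2 <- mk_fst_tbl(all_ids, fst_vals)
  draws <- t(vapply(1:30, function(i) {
    take <- sample(all_ids, 40)
    rr <- fstq_ratio(f2, take, setdiff(all_ids, take))
    c(rr$ratio, rr$p)
  }, numeric(2)))
  expect_lt(abs(mean(draws[, 1]) - 1), 0.15)
  expect_gt(mean(draws[, 2] > 0.05), 0.8)
  # under-sized top sets error
  expect_error(fstq_ratio(f, top_ids[1:5], nc_ids), "fewer than 10")
})

test_that("exchanging top and neutral labels flips t and inverts the ratio", {
  set.seed(16)
  ids <- sprintf("s%03d", 1:300)
  f <- mk_fst_tbl(ids, rbeta(300, 1, 3))
  top <- ids[1:50]
  nc <- ids[51:300]
  r1 <- fstq_ratio(f, top, nc)
  r2 <- fstq_ratio(f, nc, top)
  expect_equal(r1$ratio, 1 / r2$ratio)
  expect_equal(r1$t, -r2$t, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("cutoff scan rows match direct recomputation per cutoff", {
  fb <- demo_fixture()
  tr <- genotype_traits(fb$plants, fb$metadata)
  grp <- group_vec(tr)
  g2 <- maf_filter(fb$genotypes)
  nc <- g2$snps$snp_id[!g2$snps$coding]
  eff <- dplyr::filter(combine_effects(fb$effects), trait == "seed_mass")
  f <- wc_fst(g2, grp, pair = c("South relict", "Center cosmopolitan"))
  scan <- fstq_scan(f, eff, nc,
    cutoffs = c(0.02, 0.05), snps = fb$genotypes$snps,
    trait = "seed_mass"
  )
  expect_equal(nrow(scan), 2L)
  top05 <- select_top_snps(eff, 0.05, snps = fb$genotypes$snps)
  direct <- mean(f$fst[f$snp_id %in% top_snp_ids(top05) & is.finite(f$fst)])
  expect_equal(scan$fstq[scan$cutoff == 0.05], direct)
  # selection-enriched seed-mass architecture: elevated ratio where the top
  # set is dominated by causal SNPs
  expect_gt(scan$ratio[scan$cutoff == 0.02], 1)
})

test_that("replicate simulations show elevated seed-mass ratios under selection", {
  ratios <- vapply(1:10, function(i) {
    fb <- simulate_study(sim_config(
      n_genotypes = 40, n_snps = 1000, n_windows = 100,
      area_counts = c(south = 14, center = 12, north = 14),
      relict_fraction_by_area = c(south = 0.5, center = 0, north = 0.5),
      seed = 3000 + i
    ))
    tr <- genotype_traits(fb$plants, fb$metadata)
    g2 <- maf_filter(fb$genotypes)
    nc <- g2$snps$snp_id[!g2$snps$coding]
    eff <- dplyr::filter(combine_effects(fb$effects), trait == "seed_mass")
    top <- select_top_snps(eff, 0.02, snps = fb$genotypes$snps, trait = "seed_mass")
    f <- wc_fst(g2, group_vec(tr), pair = c("South relict", "Center cosmopolitan"))
    fstq_ratio(f, top, nc)$ratio
  }, numeric(1))
  expect_gt(mean(ratios), 1.1)
})

test_that("group-pair ratio contrasts use joint resampling and degenerate correctly", {
  set.seed(17)
  ids <- sprintf("s%03d", 1:400)
  fstv <- rbeta(400, 1, 3)
  f_dup <- dplyr::bind_rows(
    mk_fst_tbl(ids, fstv, pair = "X vs Y"),
    mk_fst_tbl(ids, fstv, pair = "X vs Z")
  )
  res <- ratio_group_contrast(f_dup, ids[1:40], ids[41:400],
    reference_pair = "X vs Y", n_boot = 100, seed = 1
  )
  # identical pair duplicated: no detectable contrast
  expect_equal(res$ratio, res$ratio_reference)
  expect_equal(res$p, 1)
  expect_error(
    ratio_group_contrast(f_dup, ids[1:40], ids[41:400], "X vs Y", n_boot = 0),
    "n_boot"
  )
  # genuinely shifted pair is detected
  f_shift <- dplyr::bind_rows(
    mk_fst_tbl(ids, fstv, pair = "X vs Y"),
    mk_fst_tbl(ids, c(fstv[1:40] * 3, fstv[41:400]), pair = "X vs Z")
  )
  res2 <- ratio_group_contrast(f_shift, ids[1:40], ids[41:400],
    reference_pair = "X vs Y", n_boot = 100, seed = 2
  )
  expect_lt(res2$p, 0.01)
  expect_gt(res2$ratio, res2$ratio_reference)
})

test_that("enrichment bootstrap: saturation, determinism, accounting and SEM scaling", {
  fb <- demo_fixture()
  tr <- genotype_traits(fb$plants, fb$metadata)
  grp <- group_vec(tr)
  nc <- fb$genotypes$snps$snp_id[!fb$genotypes$snps$coding]
  eff <- dplyr::filter(combine_effects(fb$effects), trait == "seed_mass")
  top <- select_top_snps(eff, 0.02, snps = fb$genotypes$snps, trait = "seed_mass")
  # saturation: every window outlier for every genotype -> difference 0, ratio 1
  sat <- dplyr::mutate(fb$ancestry, outlier = 1L)
  en_sat <- suppressWarnings(enrichment_bootstrap(
    top, sat, grp, nc, fb$genotypes$snps,
    n_perm = 5, n_per_cat = 100, seed = 1
  ))
  expect_true(all(en_sat$enrichment == 0))
  en_sat_r <- suppressWarnings(enrichment_bootstrap(
    top, sat, grp, nc, fb$genotypes$snps,
    n_perm = 5, n_per_cat = 100, mode = "ratio", seed = 1
  ))
  expect_true(all(en_sat_r$enrichment == 1))
  # determinism and category accounting
  en1 <- suppressWarnings(enrichment_bootstrap(
    top, fb$ancestry, grp, nc, fb$genotypes$snps,
    n_perm = 10, n_per_cat = 300, seed = 7
  ))
  en2 <- suppressWarnings(enrichment_bootstrap(
    top, fb$ancestry, grp, nc, fb$genotypes$snps,
    n_perm = 10, n_per_cat = 300, seed = 7
  ))
  expect_equal(as.data.frame(en1), as.data.frame(en2))
  expect_equal(attr(en1, "slots_per_perm"), 900L)
  # SEM shrinks with the number of permutations
  en_many <- suppressWarnings(enrichment_bootstrap(
    top, fb$ancestry, grp, nc, fb$genotypes$snps,
    n_perm = 160, n_per_cat = 300, seed = 7
  ))
  expect_lt(mean(en_many$sem), mean(en1$sem))
})

test_that("enrichment recovers the planted relict/cosmopolitan sign pattern", {
  fb <- demo_fixture() # selection + enrichment signals on
  tr <- genotype_traits(fb$plants, fb$metadata)
  grp <- group_vec(tr)
  nc <- fb$genotypes$snps$snp_id[!fb$genotypes$snps$coding]
  eff <- dplyr::filter(combine_effects(fb$effects), trait == "seed_mass")
  top <- select_top_snps(eff, 0.02, snps = fb$genotypes$snps, trait = "seed_mass")
  en <- suppressWarnings(enrichment_bootstrap(
    top, fb$ancestry, grp, nc, fb$genotypes$snps,
    n_perm = 50, n_per_cat = 500, seed = 3
  ))
  pos <- dplyr::filter(en, sign == "positive")
  rel <- grepl("relict", pos$group)
  # positive seed-mass haplotypes enriched in relicts, depleted in cosmopolitans
  expect_true(all(pos$enrichment[rel] > 0))
  expect_true(all(pos$enrichment[!rel] < 0))
  neg <- dplyr::filter(en, sign == "negative")
  expect_true(all(neg$enrichment[grepl("relict", neg$group)] < 0))
})
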