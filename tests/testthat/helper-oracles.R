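# Independent oracles and shared fixtures for the test suite.

# Weir-Cockerham theta, haploid reduction, written directly from the one-way
# ANOVA definitions with explicit per-SNP loops and sums of squared
# deviations (independent of the vectorized implementation in the package).
oracle_wc_fst <- function(x, groups) {
  labs <- unique(groups[!is.na(groups)])
  r <- length(labs)
  m <- ncol(x)
  a <- cvec <- fst <- rep(NA_real_, m)
  for (s in seq_len(m)) {
    ns <- ps <- numeric(r)
    ssw <- 0
    for (k in seq_len(r)) {
      xs <- x[groups == labs[k], s]
      xs <- xs[!is.na(xs)]
      ns[k] <- length(xs)
      ps[k] <- mean(xs)
      ssw <- ssw + sum((xs - mean(xs))^2)
    }
    N <- sum(ns)
    p_bar <- sum(ns * ps) / N
    if (any(ns == 0) || N <= r || p_bar <= 0 || p_bar >= 1) next
    msb <- sum(ns * (ps - p_bar)^2) / (r - 1)
    msw <- ssw / (N - r)
    n_c <- (N - sum(ns^2) / N) / (r - 1)
    a[s] <- (msb - msw) / n_c
    cvec[s] <- msw
    fst[s] <- a[s] / (a[s] + cvec[s])
  }
  list(a = a, c = cvec, fst = fst)
}

# Exhaustive-pairs LD pruning oracle for instances that fit in one window:
# scan every ordered pair, drop the later SNP whenever r^2 >= r2_max.
oracle_ld_prune_one_window <- function(x, r2_max) {
  kept <- rep(TRUE, ncol(x))
  for (i in seq_len(ncol(x) - 1)) {
    if (!kept[i]) next
    for (j in (i + 1):ncol(x)) {
      if (!kept[j]) next
      r <- suppressWarnings(cor(x[, i], x[, j], use = "pairwise.complete.obs"))
      if (is.finite(r) && r^2 >= r2_max) kept[j] <- FALSE
    }
  }
  kept
}

# Direct (non-package) among/within variance components on genotype means,
# used to score Q_ST estimates against generator truth.
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  labs <- unique(groups)
  n_i <- sapply(labs, function(l) sum(groups == l))
  m_i <- sapply(labs, function(l) mean(values[groups == l]))
  N <- length(values)
  grand <- mean(values)
  msb <- sum(n_i * (m_i - grand)^2) / (length(labs) - 1)
  msw <- sum((values - m_i[match(groups, labs)])^2) / (N - length(labs))
  n0 <- (N - sum(n_i^2) / N) / (length(labs) - 1)
  list(sigma2_B = max((msb - msw) / n0, 0), sigma2_W = msw)
}

random_genotype_matrix <- function(n_geno, n_snp, missing = 0, seed = NULL,
                                   span_bp = 200000L) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rbinom(n_geno * n_snp, 1L, runif(n_snp, 0.1, 0.9)[rep(
    seq_len(n_snp),
    each = n_geno
  )]), n_geno, n_snp)
  if (missing > 0) x[runif(length(x)) < missing] <- NA_integer_
  rownames(x) <- sprintf("g%02d", seq_len(n_geno))
  genotype_matrix(x, tibble::tibble(
    snp_id = sprintf("s%03d", seq_len(n_snp)), chrom = "1",
    pos = sort(sample.int(span_bp, n_snp)) - 1L,
    coding = rep(c(TRUE, FALSE), length.out = n_snp)
  ))
}

# A mid-size study fixture with the default trade-off architecture, built
# once per test run and reused across files.
.fixture_cache <- new.env(parent = emptyenv())
demo_fixture <- function() {
  if (is.null(.fixture_cache$fb)) {
    .fixture_cache$fb <- simulate_study(sim_config(
      n_snps = 1500, n_windows = 150, tradeoff_rho = -0.8, seed = 20260921
    ))
  }
  .fixture_cache$fb
}

null_fixture <- function(seed = 1) {
  simulate_study(sim_config(
    n_genotypes = 40, n_snps = 2000, n_windows = 200,
    area_counts = c(south = 14, center = 12, north = 14),
    relict_fraction_by_area = c(south = 0.5, center = 0, north = 0.5),
    selection_signal = FALSE, enrichment_signal = FALSE, seed = seed
  ))
}

group_vec <- function(traits) {
  stats::setNames(as.character(traits$group), traits$genotype_id)
}
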