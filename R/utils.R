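# Internal helpers shared across modules.

# Deterministic child seeds: one global seed in the config, one fixed offset per
# generator stage, so stages can be re-derived independently (e.g. the ancestry
# mosaic must be identical whether produced inside simulate_genomes() or by
# simulate_ancestry_windows()).
child_seed <- function(seed, stage) {
  offsets <- c(
    metadata = 1L, genome = 2L, architecture = 3L, frequencies = 4L,
    ancestry = 5L, dosage = 6L, effects = 7L, traits = 8L, pipeline = 9L
  )
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  (abs(as.integer(seed)) %% 1000000L) * 1000L + offsets[[stage]]
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# One-way random-effects ANOVA method-of-moments components with the
# unbalanced-design correction n0 = (N - sum(n_i^2)/N) / (k - 1).
# Returns among-group (sigma2_B) and within-group (sigma2_W) components;
# negative among-group moment estimates are truncated at zero and flagged.
anova_components <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups[ok])
  n_i <- tapply(values, groups, length)
  k <- length(n_i)
  N <- sum(n_i)
  if (k < 2L) stop("need at least 2 groups with data")
  if (N <= k) stop("no within-group replication: every group has a single observation")
  m_i <- tapply(values, groups, mean)
  grand <- sum(n_i * m_i) / N
  ssb <- sum(n_i * (m_i - grand)^2)
  ssw <- sum((values - m_i[groups])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  sigma2_B <- (msb - msw) / n0
  truncated <- sigma2_B < 0
  list(
    sigma2_B = max(sigma2_B, 0), sigma2_W = msw, truncated = truncated,
    n_groups = k, n_total = N, msb = msb, msw = msw, n0 = n0
  )
}

# Clip a symmetric matrix to the nearest positive semi-definite matrix by
# zeroing negative eigenvalues, then add a small ridge so Cholesky succeeds.
psd_clip <- function(m, ridge = 1e-8) {
  dn <- dimnames(m)
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  out <- out + diag(ridge * max(mean(diag(out)), 1e-12), nrow(out))
  dimnames(out) <- dn
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
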