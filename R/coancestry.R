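#' Method-of-moments coancestry matrix from neutral SNPs
#'
#' Estimates coancestry between inbred lines (and optionally between groups)
#' from standardized allele sharing relative to total-sample allele
#' frequencies: `theta_jk = mean_s (x_js - p_s)(x_ks - p_s) / (p_s (1 - p_s))`
#' over usable SNPs. By convention the neutral set is the non-coding SNPs;
#' SNPs with more than `max_missing` missingness (the 95%-genotyped
#' completeness rule) or monomorphic are excluded. The estimate is shrunk to
#' the nearest positive semi-definite matrix by eigenvalue clipping.
#'
#' With `groups`, the genotype-level matrix is averaged into a group-level
#' matrix: between-group entries average all cross pairs, within-group
#' (diagonal) entries average distinct pairs within the group (falling back to
#' the self-entry for singleton groups, with a warning).
#'
#' @param g A [genotype_matrix()].
#' @param groups Optional group labels (named vector or data frame as in
#'   [wc_fst()]); when given, a group-level matrix is returned.
#' @param max_missing Maximum per-SNP missing fraction (default 0.05).
#' @param noncoding_only Restrict to non-coding SNPs (default TRUE).
#' @return A symmetric positive semi-definite matrix of class `coancestry`
#'   with attributes `n_snps` (SNPs used) and `level`
#'   (`"genotype"`/`"group"`).
#' @export
coancestry_mom <- function(g, groups = NULL, max_missing = 0.05,
                           noncoding_only = TRUE) {
  x <- g$dosage
  use <- rep(TRUE, n_snps(g))
  if (noncoding_only && any(!g$snps$coding)) use <- use & !g$snps$coding
  miss <- colMeans(is.na(x))
  use <- use & miss <= max_missing
  p <- colMeans(x, na.rm = TRUE)
  use <- use & p > 0 & p < 1 & is.finite(p)
  if (sum(use) < 50) {
    stop(sprintf("only %d usable SNPs for coancestry (need >= 50)", sum(use)))
  }
  x <- x[, use, drop = FALSE]
  p <- p[use]
  z <- sweep(sweep(x, 2, p, "-"), 2, sqrt(p * (1 - p)), "/")
  obs <- (!is.na(z)) + 0
  z[is.na(z)] <- 0
  theta <- (z %*% t(z)) / (obs %*% t(obs))
  dimnames(theta) <- list(genotype_ids(g), genotype_ids(g))
  level <- "genotype"
  if (!is.null(groups)) {
    grp <- align_groups(g, groups)
    keep <- !is.na(grp)
    theta <- theta[keep, keep]
    grp <- grp[keep]
    labs <- sort(unique(grp))
    gt <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    for (i in seq_along(labs)) {
      for (j in seq_len(i)) {
        ii <- which(grp == labs[i])
        jj <- which(grp == labs[j])
        if (i == j) {
          if (length(ii) == 1) {
            warning("singleton group ", labs[i], ": using self-coancestry on the diagonal")
            gt[i, i] <- theta[ii, ii]
          } else {
            sub <- theta[ii, ii]
            gt[i, i] <- mean(sub[lower.tri(sub)])
          }
        } else {
          gt[i, j] <- gt[j, i] <- mean(theta[ii, jj])
        }
      }
    }
    theta <- gt
    level <- "group"
  }
  theta <- psd_clip(theta)
  structure(theta, class = c("coancestry", "matrix", "array"),
            n_snps = sum(use), level = level)
}

# Align a trait data frame into a groups x traits mean matrix.
#' Group-level trait means and pooled within-group covariance
#'
#' Helpers preparing the inputs of [s_statistic()]: `group_trait_means()`
#' averages genotype means within groups; `within_group_cov()` pools the
#' within-group covariance of genotype means (the additive G estimate for a
#' selfing panel).
#'
#' @param traits Data frame of genotype means (e.g. [genotype_traits()]).
#' @param vars Character vector of trait columns.
#' @param group Unquoted grouping column (default `group`).
#' @return `group_trait_means()`: groups x traits matrix.
#'   `within_group_cov()`: traits x traits pooled covariance matrix.
#' @export
group_trait_means <- function(traits, vars, group = group) {
  grp <- as.character(rlang::eval_tidy(rlang::enquo(group), traits))
  ok <- !is.na(grp)
  m <- sapply(vars, function(v) tapply(traits[[v]][ok], grp[ok], mean, na.rm = TRUE))
  m <- matrix(m, ncol = length(vars), dimnames = list(sort(unique(grp[ok])), vars))
  m
}

#' @rdname group_trait_means
#' @export
within_group_cov <- function(traits, vars, group = group) {
  grp <- as.character(rlang::eval_tidy(rlang::enquo(group), traits))
  x <- as.matrix(traits[, vars])
  ok <- !is.na(grp) & complete.cases(x)
  x <- x[ok, , drop = FALSE]
  grp <- grp[ok]
  labs <- unique(grp)
  acc <- matrix(0, length(vars), length(vars))
  df <- 0
  for (l in labs) {
    xi <- x[grp == l, , drop = FALSE]
    if (nrow(xi) < 2) next
    acc <- acc + cov(xi) * (nrow(xi) - 1)
    df <- df + nrow(xi) - 1
  }
  if (df == 0) stop("no group with >= 2 genotypes; cannot pool within-group covariance")
  out <- acc / df
  dimnames(out) <- list(vars, vars)
  out
}

chol_safe <- function(m, what = "matrix") {
  ridge <- 1e-10 * max(mean(diag(m)), 1e-12)
  for (i in 0:8) {
    ch <- tryCatch(chol(m + diag(ridge * 10^i * (i > 0), nrow(m))), error = function(e) NULL)
    if (!is.null(ch)) {
      if (i > 0) message(what, " ridge-regularised for Cholesky (", ridge * 10^i, ")")
      return(ch)
    }
  }
  stop(what, " is not positive definite even after ridge regularisation")
}

# Mahalanobis-type divergence of group means about the coancestry-weighted
# (GLS) ancestral mean: D = tr(Sigma^-1 d G^-1 d') with Sigma = 2 theta,
# d = M - 1 a'. Returns the divergence and the ancestral mean.
neutral_divergence <- function(m, sigma_inv, g_inv) {
  ones <- rep(1, nrow(m))
  w1 <- sigma_inv %*% ones
  a <- as.vector(t(m) %*% w1 / sum(w1))
  d <- sweep(m, 2, a, "-")
  list(D = sum((sigma_inv %*% d) * (d %*% g_inv)), ancestral = a)
}

#' Monte-Carlo drift test for trait-pair divergence (the S statistic)
#'
#' Tests whether observed among-group divergence of a pair of traits exceeds
#' the expectation under pure genetic drift. Under the neutral model, group
#' mean vectors are matrix-normal about the ancestral mean with
#' between-group covariance `2 * theta` (coancestry) and trait covariance `G`
#' (within-group genetic covariance). The ancestral mean is estimated as the
#' coancestry-weighted generalized-least-squares mean of the group means, and
#' divergence is measured by the Mahalanobis norm in the `(2 theta) x G`
#' metric. `S` is the fraction of `n_draws` neutral draws whose divergence is
#' smaller than observed: drift alone gives `S` near 0.5, directional
#' selection pushes `S` toward 1, stabilizing selection toward 0. Observed
#' and simulated means pass through the identical estimation pipeline, so `S`
#' is uniform under the neutral model by construction.
#'
#' @param group_means Groups x traits matrix (rownames = groups), e.g. from
#'   [group_trait_means()].
#' @param theta Group-level [coancestry_mom()] matrix aligned with
#'   `group_means` rows.
#' @param G Within-group genetic covariance of the traits (see
#'   [within_group_cov()]); ridge-regularised with a message if singular.
#' @param n_draws Monte-Carlo draws per trait pair (default 1000).
#' @param seed Optional seed.
#' @param pairs Optional list of trait-name pairs; default all pairs.
#' @return Tibble of class `s_statistic`: `trait1`, `trait2`, `S`, `n_draws`,
#'   `ancestral1`, `ancestral2` (estimated ancestral means). Per-pair group
#'   deviations from the ancestral mean are kept in the `"deviations"`
#'   attribute for plotting.
#' @export
s_statistic <- function(group_means, theta, G, n_draws = 1000, seed = NULL,
                        pairs = NULL) {
  m <- as.matrix(group_means)
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  theta <- as.matrix(theta)
  if (!all(rownames(m) %in% rownames(theta))) {
    stop("theta must cover all groups in group_means")
  }
  theta <- theta[rownames(m), rownames(m)]
  traits <- colnames(m)
  if (is.null(pairs)) {
    if (length(traits) < 2) stop("need at least two traits")
    pairs <- combn(traits, 2, simplify = FALSE)
  }
  sigma <- 2 * theta
  ch_sigma <- chol_safe(sigma, "coancestry (2*theta)")
  sigma_inv <- chol2inv(ch_sigma)
  n_grp <- nrow(m)
  with_seed(seed, {
    dev_list <- list()
    res <- purrr::map_dfr(pairs, function(pr) {
      g2 <- as.matrix(G)[pr, pr]
      ch_g <- chol_safe(g2, paste0("G[", paste(pr, collapse = ","), "]"))
      g_inv <- chol2inv(ch_g)
      obs <- neutral_divergence(m[, pr, drop = FALSE], sigma_inv, g_inv)
      d_star <- vapply(seq_len(n_draws), function(b) {
        z <- matrix(rnorm(n_grp * 2), n_grp, 2)
        sim <- sweep(t(ch_sigma) %*% z %*% ch_g, 2, obs$ancestral, "+")
        neutral_divergence(sim, sigma_inv, g_inv)$D
      }, numeric(1))
      dev_list[[paste(pr, collapse = "|")]] <<- tibble(
        trait1 = pr[1], trait2 = pr[2], group = rownames(m),
        dev1 = m[, pr[1]] - obs$ancestral[1], dev2 = m[, pr[2]] - obs$ancestral[2]
      )
      tibble(
        trait1 = pr[1], trait2 = pr[2], S = mean(d_star < obs$D),
        n_draws = n_draws,
        ancestral1 = obs$ancestral[1], ancestral2 = obs$ancestral[2]
      )
    })
    structure(
      res,
      class = c("s_statistic", class(res)),
      deviations = dplyr::bind_rows(dev_list)
    )
  })
}
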