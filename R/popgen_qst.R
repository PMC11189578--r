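#' Q_ST of a quantitative trait among groups
#'
#' Among/within genetic-variance ratio computed from genotype means by the
#' one-way ANOVA method-of-moments (unbalanced-design correction; negative
#' among-group components truncated at zero and flagged). For a predominantly
#' selfing species genotype means carry total genotypic variance, so the
#' default denominator is `sigma2_B + sigma2_W` (`mode = "selfing"`); the
#' classic outcrossing form `sigma2_B / (sigma2_B + 2 sigma2_W)` is available
#' with `mode = "outcrossing"`.
#'
#' @param values Numeric genotype means for one trait.
#' @param groups Group label per genotype.
#' @param mode `"selfing"` (default) or `"outcrossing"`.
#' @param trait Optional trait name carried into the result.
#' @return Object of class `qst_result` with `sigma2_B`, `sigma2_W`, `qst`,
#'   `mode`, `truncated`.
#' @export
#' @examples
#' qst(c(1, 1.1, 5, 5.2), c("a", "a", "b", "b"))$qst
qst <- function(values, groups, mode = c("selfing", "outcrossing"), trait = NULL) {
  mode <- match.arg(mode)
  sizes <- table(groups[!is.na(groups) & is.finite(values)])
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("qst needs >= 2 groups with >= 2 genotypes each")
  }
  comp <- anova_components(values, groups)
  denom <- comp$sigma2_B +
    (if (mode == "selfing") 1 else 2) * comp$sigma2_W
  q <- if (denom <= 0) {
    warning("zero total variance: Q_ST undefined")
    NA_real_
  } else {
    comp$sigma2_B / denom
  }
  structure(
    list(
      trait = trait, sigma2_B = comp$sigma2_B, sigma2_W = comp$sigma2_W,
      qst = q, mode = mode, truncated = comp$truncated,
      n_groups = comp$n_groups, n_genotypes = comp$n_total
    ),
    class = "qst_result"
  )
}

#' @export
print.qst_result <- function(x, ...) {
  cat(sprintf(
    "<qst_result>%s Q_ST = %.3f (sigma2_B = %.4g, sigma2_W = %.4g, %s mode)%s\n",
    if (is.null(x$trait)) "" else paste0(" ", x$trait, ":"),
    x$qst, x$sigma2_B, x$sigma2_W, x$mode,
    if (x$truncated) " [truncated]" else ""
  ))
  invisible(x)
}

#' Bootstrap test of Q_ST against the genomic F_ST distribution
#'
#' Non-parametric check of whether a trait's Q_ST is extreme in the per-SNP
#' F_ST distribution. Each bootstrap replicate resamples genotypes within
#' groups (recomputing Q_ST) and draws one SNP's F_ST from the genomic
#' distribution; the reported p is the add-one-corrected probability that a
#' neutral F_ST draw is at least as large as the Q_ST draw. Small p means
#' trait differentiation exceeds the neutral genomic background (directional
#' selection); the observed Q_ST's quantile in the F_ST distribution is also
#' reported.
#'
#' @param values,groups,mode As in [qst()].
#' @param fst Per-SNP F_ST values: a numeric vector or an `fst_result` tibble
#'   (its `fst` column is used; `NA`s dropped).
#' @param n_boot Bootstrap replicates (default 1000; < 100 warns).
#' @param seed Optional seed.
#' @param trait Optional trait name.
#' @return Object of class `qst_fst_test`: `qst` (observed), `quantile` (of
#'   Q_ST in the F_ST distribution), `p`, `n_boot`, plus the bootstrap draws.
#' @export
qst_fst_test <- function(values, groups, fst, n_boot = 1000,
                         mode = c("selfing", "outcrossing"), seed = NULL,
                         trait = NULL) {
  mode <- match.arg(mode)
  if (inherits(fst, "data.frame")) fst <- fst$fst
  fst <- fst[is.finite(fst)]
  if (!length(fst)) stop("no finite F_ST values supplied")
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (n_boot < 100) warning("n_boot < 100 gives a coarse empirical p-value")
  obs <- qst(values, groups, mode = mode, trait = trait)
  groups <- as.character(groups)
  idx_by_group <- split(seq_along(values), groups)
  with_seed(seed, {
    qst_draws <- vapply(seq_len(n_boot), function(b) {
      take <- unlist(lapply(idx_by_group, function(ii) {
        sample(ii, length(ii), replace = TRUE)
      }), use.names = FALSE)
      res <- tryCatch(
        suppressWarnings(qst(values[take], groups[take], mode = mode)$qst),
        error = function(e) NA_real_
      )
      res
    }, numeric(1))
    fst_draws <- sample(fst, n_boot, replace = TRUE)
    ok <- is.finite(qst_draws)
    p <- (1 + sum(fst_draws[ok] >= qst_draws[ok])) / (sum(ok) + 1)
    structure(
      list(
        trait = trait, qst = obs$qst, mode = mode,
        quantile = mean(fst <= obs$qst), p = p, n_boot = n_boot,
        qst_draws = qst_draws, fst_draws = fst_draws
      ),
      class = "qst_fst_test"
    )
  })
}

#' @export
print.qst_fst_test <- function(x, ...) {
  cat(sprintf(
    "<qst_fst_test>%s Q_ST = %.3f at quantile %.3f of the F_ST distribution; P(F_ST >= Q_ST) = %.4f (%d bootstrap replicates)\n",
    if (is.null(x$trait)) "" else paste0(" ", x$trait, ":"),
    x$qst, x$quantile, x$p, x$n_boot
  ))
  invisible(x)
}
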