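#' Combine sparse-model effect components into total SNP effects
#'
#' Each SNP's total effect on a trait combines the polygenic ("small") effect
#' `alpha`, the sparse ("large") effect `beta` and the posterior inclusion
#' probability `delta`: `E = alpha + beta * delta`. Missing components
#' propagate to missing `E`.
#'
#' @param effects Tibble with columns `alpha`, `beta`, `delta` (one row per
#'   SNP x trait). `delta` outside \[0, 1\] is an error.
#' @return The input with an `E` column added (replaced if present).
#' @export
#' @examples
#' combine_effects(tibble::tibble(alpha = 0.1, beta = 2, delta = 0.5))$E # 1.1
combine_effects <- function(effects) {
  stopifnot(all(c("alpha", "beta", "delta") %in% names(effects)))
  d <- effects$delta
  if (any(d < 0 | d > 1, na.rm = TRUE)) {
    stop("delta (inclusion probability) must lie in [0, 1]")
  }
  dplyr::mutate(effects, E = .data$alpha + .data$beta * .data$delta)
}

#' Select symmetric top-effect SNP tails
#'
#' Extracts the SNPs with the strongest positive and strongest negative total
#' effects on a trait: each tail holds `ceiling(fraction / 2 * n_snps)` SNPs
#' (so `fraction = 0.01` on 474,708 SNPs gives 2 x 2374 = 4748), ranked on
#' signed `E` with deterministic `(chrom, pos)` tie-breaking. Ties spanning a
#' tail boundary are resolved by coordinate order with a warning.
#'
#' @param effects Tibble with `snp_id` and `E` for one trait (filter
#'   multi-trait tables first); optional `chrom`/`pos` columns (or supply
#'   `snps`) control tie-breaking.
#' @param fraction Total top fraction split evenly between tails (default
#'   0.01, i.e. 0.5% per tail).
#' @param snps Optional SNP annotation tibble (`snp_id`, `chrom`, `pos`) used
#'   for tie-breaking when `effects` lacks coordinates.
#' @param trait Optional trait name carried into the result.
#' @return Object of class `top_snp_set`: list with `trait`, `fraction`,
#'   `positive` and `negative` (disjoint `snp_id` vectors of equal size).
#' @export
select_top_snps <- function(effects, fraction = 0.01, snps = NULL, trait = NULL) {
  stopifnot(all(c("snp_id", "E") %in% names(effects)))
  if (!is.null(snps)) {
    effects <- dplyr::left_join(
      effects, dplyr::select(snps, "snp_id", "chrom", "pos"),
      by = "snp_id"
    )
  }
  if (!all(c("chrom", "pos") %in% names(effects))) {
    effects$chrom <- "0"
    effects$pos <- seq_len(nrow(effects))
  }
  e <- effects$E
  n <- sum(!is.na(e))
  if (n < 2 / fraction) stop("need at least 2/fraction SNPs with defined effects")
  m <- ceiling(fraction / 2 * n)
  if (2 * m > n) stop("tail size exceeds half the SNP count")
  ord_coord <- order(effects$chrom, effects$pos)
  ranked <- effects[ord_coord, ]
  pos_tail <- ranked$snp_id[order(-ranked$E)][seq_len(m)]
  # ties spanning both tails (degenerate flat effect vectors) go to the
  # positive tail first; the negative tail takes the next coordinate-ordered
  # candidates so the tails stay disjoint
  neg_tail <- setdiff(ranked$snp_id[order(ranked$E)], pos_tail)[seq_len(m)]
  e_sorted <- sort(e, decreasing = TRUE)
  boundary_tie <- (m < n) &&
    (e_sorted[m] == e_sorted[m + 1] || e_sorted[n - m + 1] == e_sorted[n - m])
  if (boundary_tie) {
    warning("tied effect values at a tail boundary; resolved by (chrom, pos) order")
  }
  if (anyNA(neg_tail) || length(intersect(pos_tail, neg_tail))) {
    stop("tails overlap; fraction too large for this SNP set")
  }
  structure(
    list(trait = trait, fraction = fraction, positive = pos_tail, negative = neg_tail),
    class = "top_snp_set"
  )
}

#' @export
print.top_snp_set <- function(x, ...) {
  cat(sprintf(
    "<top_snp_set>%s %d + %d SNPs (total fraction %.3g)\n",
    if (is.null(x$trait)) "" else paste0(" ", x$trait, ":"),
    length(x$positive), length(x$negative), x$fraction
  ))
  invisible(x)
}

#' All SNP ids in a top set
#' @param x A `top_snp_set`.
#' @return Character vector (positive tail then negative tail).
#' @export
top_snp_ids <- function(x) c(x$positive, x$negative)

#' Correlations between SNP effects on two traits
#'
#' Pearson correlation of total SNP effects `E` between trait pairs, either
#' genome-wide or restricted to the union of the two traits' top sets (where
#' trade-off signals concentrate).
#'
#' @param effects Long tibble with `snp_id`, `trait`, `E` (run
#'   [combine_effects()] first if needed).
#' @param traits Character vector of traits to correlate (default: all).
#' @param scope `"genome"` or `"top"`.
#' @param top_sets Named list of [select_top_snps()] results per trait;
#'   required for `scope = "top"`.
#' @return Tibble with `trait1`, `trait2`, `scope`, `n`, `r`, `p` for every
#'   unordered pair.
#' @export
effect_correlations <- function(effects, traits = NULL,
                                scope = c("genome", "top"), top_sets = NULL) {
  scope <- match.arg(scope)
  if (!"E" %in% names(effects)) effects <- combine_effects(effects)
  traits <- traits %||% unique(effects$trait)
  if (scope == "top" && is.null(top_sets)) {
    stop("scope = 'top' needs top_sets (named list of top_snp_set per trait)")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(effects, "snp_id", "trait", "E"),
    names_from = "trait", values_from = "E"
  )
  purrr::map_dfr(combn(traits, 2, simplify = FALSE), function(pr) {
    d <- wide
    if (scope == "top") {
      ids <- union(top_snp_ids(top_sets[[pr[1]]]), top_snp_ids(top_sets[[pr[2]]]))
      d <- dplyr::filter(d, .data$snp_id %in% ids)
    }
    x <- d[[pr[1]]]
    y <- d[[pr[2]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      warning("constant or insufficient effects for ", pr[1], " vs ", pr[2])
      return(tibble(
        trait1 = pr[1], trait2 = pr[2], scope = scope, n = sum(ok),
        r = NA_real_, p = NA_real_
      ))
    }
    ct <- cor.test(x[ok], y[ok])
    tibble(
      trait1 = pr[1], trait2 = pr[2], scope = scope, n = sum(ok),
      r = unname(ct$estimate), p = ct$p.value
    )
  })
}

#' Overlap between two traits' top-SNP sets
#'
#' Counts shared SNPs by tail combination and tests total overlap against the
#' hypergeometric expectation for random draws from the same SNP universe.
#'
#' @param a,b [select_top_snps()] results on the same SNP universe.
#' @param n_snps Size of the shared SNP universe.
#' @return List of class `top_overlap`: 2x2 count matrix `counts` (rows = A
#'   tails, columns = B tails), `total` shared SNPs, `expected` under random
#'   draws and hypergeometric enrichment `p`.
#' @export
top_overlap <- function(a, b, n_snps) {
  counts <- matrix(
    c(
      length(intersect(a$positive, b$positive)),
      length(intersect(a$positive, b$negative)),
      length(intersect(a$negative, b$positive)),
      length(intersect(a$negative, b$negative))
    ),
    2, 2, byrow = TRUE,
    dimnames = list(c("A_positive", "A_negative"), c("B_positive", "B_negative"))
  )
  ids_a <- top_snp_ids(a)
  ids_b <- top_snp_ids(b)
  total <- length(intersect(ids_a, ids_b))
  expected <- length(ids_a) * length(ids_b) / n_snps
  p <- phyper(total - 1, length(ids_a), n_snps - length(ids_a),
    length(ids_b),
    lower.tail = FALSE
  )
  structure(
    list(counts = counts, total = total, expected = expected, p = p),
    class = "top_overlap"
  )
}

#' @export
print.top_overlap <- function(x, ...) {
  cat(sprintf(
    "<top_overlap> %d shared SNPs (%.1f expected at random), hypergeometric P = %.3g\n",
    x$total, x$expected, x$p
  ))
  print(x$counts)
  invisible(x)
}
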