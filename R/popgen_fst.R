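#' Minor-allele-frequency filter
#'
#' Keeps a SNP iff its minor allele frequency, computed from non-missing
#' calls, is strictly greater than the threshold ("superior to 5%" by
#' default); monomorphic SNPs and SNPs exactly at the threshold are removed.
#'
#' @param g A [genotype_matrix()].
#' @param threshold MAF threshold (default 0.05, strict inequality).
#' @return A filtered `genotype_matrix`; errors (with counts) if nothing
#'   survives.
#' @export
maf_filter <- function(g, threshold = 0.05) {
  p <- allele_freq(g)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > threshold
  if (!any(keep)) {
    stop(sprintf(
      "MAF filter removed all %d SNPs (threshold %.3f, strict)", n_snps(g), threshold
    ))
  }
  subset_snps(g, g$snps$snp_id[keep])
}

#' Greedy sliding-window LD pruning
#'
#' PLINK-style pruning: within each window of `window_bp` base pairs
#' (windows start every `step_snps` SNPs, scanning left to right within each
#' chromosome), the later SNP of any pair with squared Pearson correlation
#' `r^2 >= r2_max` is dropped. The scan is deterministic. Positions must be
#' sorted within chromosome; unsorted input is an error, never silently
#' sorted.
#'
#' @param g A [genotype_matrix()].
#' @param r2_max Pruning threshold; pairs at or above it lose their later SNP
#'   (default 0.1, i.e. the kept set satisfies `r^2 < 0.1`).
#' @param window_bp Window span in bp (default 50000).
#' @param step_snps Window step in SNPs (default 50).
#' @return Character vector of kept `snp_id`s, in map order.
#' @export
ld_prune <- function(g, r2_max = 0.1, window_bp = 50000, step_snps = 50) {
  snps <- g$snps
  kept <- rep(TRUE, nrow(snps))
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    pos <- snps$pos[idx]
    if (is.unsorted(pos)) {
      stop("positions not sorted within chromosome ", ch, "; refusing to sort silently")
    }
    m <- length(idx)
    starts <- seq(1L, m, by = step_snps)
    for (s in starts) {
      hi <- s + findInterval(pos[s] + window_bp - 1e-9, pos[s:m]) - 1L
      win <- s:hi
      win <- win[kept[idx[win]]]
      if (length(win) < 2) next
      cm <- suppressWarnings(
        cor(g$dosage[, idx[win], drop = FALSE], use = "pairwise.complete.obs")
      )
      cm[!is.finite(cm)] <- 0
      for (a in seq_len(length(win) - 1)) {
        if (!kept[idx[win[a]]]) next
        for (b in seq((a + 1), length(win))) {
          if (kept[idx[win[b]]] && cm[a, b]^2 >= r2_max) {
            kept[idx[win[b]]] <- FALSE
          }
        }
      }
    }
  }
  snps$snp_id[kept]
}

# group membership helper: accepts a named vector (names = genotype ids) or a
# data frame with genotype_id + group columns; returns a character vector
# aligned to genotype_ids(g).
align_groups <- function(g, groups) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$genotype_id)
  }
  if (is.null(names(groups))) {
    stopifnot(length(groups) == n_genotypes(g))
    return(setNames(as.character(groups), genotype_ids(g)))
  }
  out <- as.character(groups[genotype_ids(g)])
  setNames(out, genotype_ids(g))
}

#' Weir-Cockerham F_ST for inbred (haploid-coded) lines
#'
#' Per-SNP variance-components estimator of Weir and Cockerham's theta in its
#' haploid reduction: each fully inbred line contributes a single allele, so
#' the individual-within-population level collapses and the
#' heterozygosity component is identically zero. Per SNP, with `r` groups of
#' sizes `n_i` and allele frequencies `p_i`:
#' `MSB = sum(n_i (p_i - p_bar)^2) / (r - 1)`,
#' `MSW = sum(n_i p_i (1 - p_i)) / (N - r)`,
#' `n_c = (N - sum(n_i^2) / N) / (r - 1)`,
#' among-group component `a = (MSB - MSW) / n_c`, within component `c = MSW`,
#' and `theta = a / (a + c)`. SNPs monomorphic across the analysed groups are
#' undefined (`NA`) and excluded from summaries. The genome-wide estimate is
#' the ratio of sums `sum(a) / sum(a + c)` (attribute `fst_overall`), not the
#' mean of per-SNP ratios.
#'
#' @param g A [genotype_matrix()].
#' @param groups Group labels: named character vector (names = genotype ids)
#'   or data frame with `genotype_id` and `group`.
#' @param pair Optional character vector of 2+ group labels to analyse; by
#'   default all groups with at least 2 genotyped lines. Both/all analysed
#'   groups must have >= 2 lines.
#' @return Tibble of class `fst_result` with columns `snp_id`, `chrom`,
#'   `pos`, `pair`, `a`, `b` (always 0 in the haploid reduction), `c`, `fst`;
#'   attributes `fst_overall`, `groups`, `n_by_group`.
#' @export
wc_fst <- function(g, groups, pair = NULL) {
  grp <- align_groups(g, groups)
  use_groups <- pair %||% sort(unique(grp[!is.na(grp)]))
  if (length(use_groups) < 2) stop("need at least two groups")
  rows <- which(grp %in% use_groups)
  grp <- grp[rows]
  sizes <- table(grp)
  if (any(sizes < 2)) {
    stop(
      "each analysed group needs >= 2 genotypes; too small: ",
      paste(names(sizes)[sizes < 2], collapse = ", ")
    )
  }
  x <- g$dosage[rows, , drop = FALSE]
  r <- length(use_groups)
  obs <- !is.na(x)
  n_i <- rowsum(obs + 0, grp) # r x m non-missing counts
  x0 <- x
  x0[!obs] <- 0L
  sums <- rowsum(x0, grp)
  p_i <- sums / n_i
  p_i[n_i == 0] <- NA
  N <- colSums(n_i)
  p_bar <- colSums(sums) / N
  msb <- colSums(n_i * sweep(p_i, 2, p_bar, "-")^2, na.rm = TRUE) / (r - 1)
  msw <- colSums(n_i * p_i * (1 - p_i), na.rm = TRUE) / (N - r)
  n_c <- (N - colSums(n_i^2) / N) / (r - 1)
  a <- (msb - msw) / n_c
  cc <- msw
  fst <- a / (a + cc)
  # undefined: monomorphic across the analysed groups, a group with no calls,
  # or no within-group replication left after missingness
  bad <- p_bar <= 0 | p_bar >= 1 | !is.finite(p_bar) |
    colSums(n_i == 0) > 0 | (N - r) <= 0
  fst[bad] <- NA_real_
  a[bad] <- NA_real_
  cc[bad] <- NA_real_
  pair_label <- paste(use_groups, collapse = " vs ")
  out <- tibble(
    snp_id = g$snps$snp_id, chrom = g$snps$chrom, pos = g$snps$pos,
    pair = pair_label, a = unname(a), b = 0, c = unname(cc), fst = unname(fst)
  )
  ok <- !is.na(out$a)
  structure(
    out,
    class = c("fst_result", class(out)),
    fst_overall = sum(out$a[ok]) / sum(out$a[ok] + out$c[ok]),
    groups = use_groups,
    n_by_group = as.integer(sizes[use_groups])
  )
}

#' All pairwise Weir-Cockerham F_ST scans
#'
#' Runs [wc_fst()] for every pair of groups with at least 2 genotypes and
#' stacks the per-SNP results.
#'
#' @inheritParams wc_fst
#' @param pairs Optional list of length-2 character vectors; defaults to all
#'   qualifying pairs.
#' @return Tibble of stacked per-SNP results with a `pair` column; attribute
#'   `fst_overall` is a named vector of genome-wide ratio-of-sums estimates
#'   per pair.
#' @export
wc_fst_pairs <- function(g, groups, pairs = NULL) {
  grp <- align_groups(g, groups)
  sizes <- table(grp[!is.na(grp)])
  eligible <- names(sizes)[sizes >= 2]
  if (is.null(pairs)) {
    pairs <- combn(sort(eligible), 2, simplify = FALSE)
  }
  res <- purrr::map(pairs, function(pr) wc_fst(g, groups, pair = pr))
  overall <- vapply(res, function(x) attr(x, "fst_overall"), numeric(1))
  names(overall) <- vapply(res, function(x) x$pair[1], character(1))
  out <- dplyr::bind_rows(res)
  structure(out, class = c("fst_result", class(out)), fst_overall = overall)
}
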