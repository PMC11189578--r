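#' F_STQ / F_ST ratio for one trait's top SNPs
#'
#' `F_STQ` is the arithmetic mean of per-SNP F_ST over a trait's top-effect
#' SNPs (the field convention for this quantity, although a ratio-of-sums
#' summary is statistically preferable and available via `summary_fun`);
#' `F_ST` is the corresponding mean over non-coding (neutral baseline) SNPs.
#' Their ratio is near 1 when top SNPs are exchangeable with the neutral
#' background and above 1 under directional selection on the trait.
#' Significance uses a Welch two-sample t test between the two per-SNP F_ST
#' samples (per-SNP F_ST is heavy-tailed, so pooled-variance t is avoided).
#'
#' @param fst Per-SNP F_ST for one group pair: an `fst_result` tibble from
#'   [wc_fst()] (or any tibble with `snp_id` and `fst`).
#' @param top A [select_top_snps()] result or character vector of top SNP
#'   ids. Any top SNPs present in `noncoding` are removed from the baseline
#'   so the two sets are disjoint.
#' @param noncoding Character vector of non-coding SNP ids.
#' @param summary_fun `"mean"` (default, per the F_STQ definition) or
#'   `"ratio_of_sums"` (uses the `a` and `c` variance components).
#' @param cutoff Cutoff label carried into the result (e.g. 0.01).
#' @return One-row tibble of class `fstq_result`: `trait`, `pair`, `cutoff`,
#'   `n_top`, `n_noncoding`, `fstq`, `fst_neutral`, `ratio`, `t`, `df`, `p`.
#' @export
fstq_ratio <- function(fst, top, noncoding, summary_fun = c("mean", "ratio_of_sums"),
                       cutoff = NA_real_) {
  summary_fun <- match.arg(summary_fun)
  trait <- NULL
  if (inherits(top, "top_snp_set")) {
    trait <- top$trait
    cutoff <- if (is.na(cutoff)) top$fraction else cutoff
    top <- top_snp_ids(top)
  }
  noncoding <- setdiff(noncoding, top)
  d_top <- dplyr::filter(fst, .data$snp_id %in% top, is.finite(.data$fst))
  d_nc <- dplyr::filter(fst, .data$snp_id %in% noncoding, is.finite(.data$fst))
  if (nrow(d_top) < 10) {
    stop("top set has fewer than 10 SNPs with defined F_ST")
  }
  if (nrow(d_nc) < 10) stop("non-coding baseline has fewer than 10 SNPs with defined F_ST")
  if (summary_fun == "mean") {
    fstq <- mean(d_top$fst)
    fst_nc <- mean(d_nc$fst)
  } else {
    fstq <- sum(d_top$a) / sum(d_top$a + d_top$c)
    fst_nc <- sum(d_nc$a) / sum(d_nc$a + d_nc$c)
  }
  tt <- tryCatch(t.test(d_top$fst, d_nc$fst), error = function(e) NULL)
  if (is.null(tt)) {
    # degenerate zero-variance samples: the t statistic diverges
    diffm <- mean(d_top$fst) - mean(d_nc$fst)
    tt <- list(
      statistic = c(t = sign(diffm) * Inf), parameter = c(df = NA_real_),
      p.value = if (diffm == 0) 1 else 0
    )
  }
  out <- tibble(
    trait = trait %||% NA_character_,
    pair = fst$pair[1] %||% NA_character_,
    cutoff = cutoff,
    n_top = nrow(d_top), n_noncoding = nrow(d_nc),
    fstq = fstq, fst_neutral = fst_nc, ratio = fstq / fst_nc,
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    summary_fun = summary_fun
  )
  structure(out, class = c("fstq_result", class(out)))
}

#' Cutoff-sensitivity F_STQ / F_ST scan
#'
#' Re-derives the top set at several total cutoff fractions (0.5%, 1%, 2%,
#' 5% by default) and computes [fstq_ratio()] for each, for one trait and one
#' group pair.
#'
#' @param fst Per-SNP F_ST tibble for one group pair.
#' @param effects Effect tibble for one trait (`snp_id`, `E`; see
#'   [combine_effects()]).
#' @param noncoding Non-coding SNP ids.
#' @param cutoffs Total top fractions (default `c(0.005, 0.01, 0.02, 0.05)`).
#' @param snps Optional SNP annotation for tie-breaking.
#' @param trait Trait label.
#' @param skip_small Skip (with a warning) cutoffs whose top set is too small
#'   instead of erroring; at least one cutoff must survive.
#' @inheritParams fstq_ratio
#' @return `fstq_result` tibble with one row per cutoff.
#' @export
fstq_scan <- function(fst, effects, noncoding,
                      cutoffs = c(0.005, 0.01, 0.02, 0.05), snps = NULL,
                      trait = NULL, summary_fun = c("mean", "ratio_of_sums"),
                      skip_small = FALSE) {
  summary_fun <- match.arg(summary_fun)
  res <- purrr::map_dfr(cutoffs, function(f) {
    one <- function() {
      top <- select_top_snps(effects, fraction = f, snps = snps, trait = trait)
      fstq_ratio(fst, top, noncoding, summary_fun = summary_fun, cutoff = f)
    }
    if (skip_small) {
      tryCatch(one(), error = function(e) {
        warning(sprintf("cutoff %.3g skipped: %s", f, conditionMessage(e)))
        NULL
      })
    } else {
      one()
    }
  })
  if (!nrow(res)) stop("no usable cutoff for this trait/pair")
  structure(res, class = c("fstq_result", class(res)))
}

#' Bootstrap contrast of F_STQ / F_ST ratios between group pairs
#'
#' Compares the F_STQ/F_ST ratio of a reference group pair against every
#' other pair for the same trait. Each bootstrap replicate resamples the top
#' set and the non-coding baseline once and applies the same resampled SNPs
#' to every pair (joint resampling, preserving the dependence induced by the
#' shared SNP sets); pairwise significance uses Welch t tests between the
#' reference pair's bootstrap ratio distribution and each other pair's.
#'
#' @param fst_pairs Stacked per-SNP F_ST tibble with a `pair` column, e.g.
#'   from [wc_fst_pairs()].
#' @param top A [select_top_snps()] result or vector of top SNP ids.
#' @param noncoding Non-coding SNP ids (top SNPs are removed from it).
#' @param reference_pair The `pair` label to contrast against.
#' @param n_boot Bootstrap replicates (must be >= 1; default 200).
#' @param seed Optional seed.
#' @return Tibble with one row per non-reference pair: bootstrap mean ratios,
#'   Welch `t` and `p`. Attribute `"boot"` holds the per-replicate ratios.
#' @export
ratio_group_contrast <- function(fst_pairs, top, noncoding, reference_pair,
                                 n_boot = 200, seed = NULL) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (inherits(top, "top_snp_set")) top <- top_snp_ids(top)
  noncoding <- setdiff(noncoding, top)
  pairs <- unique(fst_pairs$pair)
  if (!reference_pair %in% pairs) stop("reference pair not found: ", reference_pair)
  wide <- fst_pairs %>%
    dplyr::select("snp_id", "pair", "fst") %>%
    tidyr::pivot_wider(names_from = "pair", values_from = "fst")
  top_rows <- which(wide$snp_id %in% top)
  nc_rows <- which(wide$snp_id %in% noncoding)
  if (length(top_rows) < 10 || length(nc_rows) < 10) {
    stop("need >= 10 top and >= 10 non-coding SNPs")
  }
  fmat <- as.matrix(wide[, pairs, drop = FALSE])
  with_seed(seed, {
    boot <- vapply(seq_len(n_boot), function(b) {
      it <- sample(top_rows, length(top_rows), replace = TRUE)
      inc <- sample(nc_rows, length(nc_rows), replace = TRUE)
      colMeans(fmat[it, , drop = FALSE], na.rm = TRUE) /
        colMeans(fmat[inc, , drop = FALSE], na.rm = TRUE)
    }, numeric(length(pairs)))
    boot <- matrix(boot, nrow = length(pairs), dimnames = list(pairs, NULL))
    ref <- boot[reference_pair, ]
    res <- purrr::map_dfr(setdiff(pairs, reference_pair), function(pr) {
      tt <- t.test(ref, boot[pr, ])
      tibble(
        pair = pr, reference = reference_pair,
        ratio = mean(boot[pr, ]), ratio_reference = mean(ref),
        t = unname(tt$statistic), p = tt$p.value, n_boot = n_boot
      )
    })
    structure(res, boot = boot)
  })
}

#' Outlier-haplotype enrichment bootstrap
#'
#' Tests whether a trait's top-effect SNPs sit in outlier (relict-ancestry)
#' 10-kb windows more often than the neutral genomic background, per
#' biogeographical group. Each of `n_perm` permutations samples `n_per_cat`
#' SNPs from each of three categories — the positive-effect tail, the
#' negative-effect tail, and random non-coding SNPs (without replacement when
#' the category is large enough, with replacement and a warning otherwise).
#' For each genotype the fraction of sampled SNPs lying in outlier windows is
#' computed from that genotype's ancestry track; group proportions average
#' over genotypes first, then enrichment is summarised over permutations
#' (mean +/- SEM). Enrichment is the difference between the top-tail and
#' non-coding proportions, reported in percentage points (`mode =
#' "difference"`, null centred at 0) or their ratio (`mode = "ratio"`, null
#' centred at 1).
#'
#' @param top A [select_top_snps()] result for one trait.
#' @param ancestry BED-like ancestry tibble (`genotype_id`, `chrom`, `start`,
#'   `end`, `outlier`), e.g. [simulate_ancestry_windows()].
#' @param groups Named group labels (names = genotype ids) or data frame with
#'   `genotype_id`, `group`.
#' @param noncoding Non-coding SNP ids.
#' @param snps SNP annotation tibble (`snp_id`, `chrom`, `pos`) used to map
#'   SNPs to windows (`floor(pos / 10000)`, half-open).
#' @param n_perm Number of permutations (default 50).
#' @param n_per_cat SNPs sampled per category per permutation (default 1000).
#' @param mode `"difference"` (default) or `"ratio"`.
#' @param seed Optional seed.
#' @return Tibble of class `enrichment_result`: one row per group x effect
#'   sign with `prop_top`, `prop_noncoding`, `enrichment`, `sem`, `n_perm`,
#'   `mode`. Attributes: `"perms"` (per-permutation values) and
#'   `"slots_per_perm"` (always `3 * n_per_cat`).
#' @export
enrichment_bootstrap <- function(top, ancestry, groups, noncoding, snps,
                                 n_perm = 50, n_per_cat = 1000,
                                 mode = c("difference", "ratio"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(top, "top_snp_set"))
  noncoding <- setdiff(noncoding, top_snp_ids(top))

  # genotype x window outlier matrix
  ancestry <- dplyr::mutate(ancestry, window = paste(.data$chrom, .data$start %/% 10000L))
  gids <- sort(unique(ancestry$genotype_id))
  wins <- sort(unique(ancestry$window))
  omat <- matrix(NA_real_, length(gids), length(wins), dimnames = list(gids, wins))
  omat[cbind(
    match(ancestry$genotype_id, gids),
    match(ancestry$window, wins)
  )] <- ancestry$outlier

  snp_win <- setNames(paste(snps$chrom, snps$pos %/% 10000L), snps$snp_id)
  cats <- list(
    positive = top$positive, negative = top$negative, noncoding = noncoding
  )
  for (nm in names(cats)) {
    w <- snp_win[cats[[nm]]]
    if (anyNA(w) || !all(w %in% wins)) {
      stop("category '", nm, "' contains SNPs without an ancestry window")
    }
  }

  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$genotype_id)
  }
  grp <- groups[gids]
  covered <- rowSums(is.na(omat)) == 0
  if (any(!covered)) {
    message(sum(!covered), " genotype(s) lack full window coverage; excluded from group means")
  }
  usable <- covered & !is.na(grp)
  glabs <- sort(unique(grp[usable]))

  small <- names(cats)[vapply(cats, length, integer(1)) < n_per_cat]
  if (length(small)) {
    warning(
      "category(ies) smaller than n_per_cat sampled with replacement: ",
      paste(small, collapse = ", ")
    )
  }

  with_seed(seed, {
    # perms[[cat]]: group x perm matrix of outlier proportions
    perms <- purrr::map(cats, function(ids) {
      out <- matrix(NA_real_, length(glabs), n_perm, dimnames = list(glabs, NULL))
      for (b in seq_len(n_perm)) {
        take <- if (length(ids) < n_per_cat) {
          sample(ids, n_per_cat, replace = TRUE)
        } else {
          sample(ids, n_per_cat, replace = FALSE)
        }
        col_idx <- match(snp_win[take], wins)
        geno_prop <- rowMeans(omat[usable, col_idx, drop = FALSE])
        out[, b] <- tapply(geno_prop, grp[usable], mean)[glabs]
      }
      out
    })
    enr <- function(top_mat) {
      if (mode == "difference") {
        100 * (top_mat - perms$noncoding)
      } else {
        top_mat / perms$noncoding
      }
    }
    res <- purrr::map_dfr(c("positive", "negative"), function(sgn) {
      e <- enr(perms[[sgn]])
      tibble(
        trait = top$trait %||% NA_character_,
        group = glabs, sign = sgn, mode = mode,
        prop_top = rowMeans(perms[[sgn]]),
        prop_noncoding = rowMeans(perms$noncoding),
        enrichment = rowMeans(e),
        sem = apply(e, 1, sd) / sqrt(n_perm),
        n_perm = n_perm
      )
    })
    structure(
      res,
      class = c("enrichment_result", class(res)),
      perms = perms, slots_per_perm = 3L * n_per_cat
    )
  })
}
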