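# ggplot2 autoplot methods for the main result types.

#' Plot genotype traits: the fecundity / seed-mass trade-off
#'
#' Scatter of genotype-mean seed mass against fecundity under control,
#' coloured by biogeographical group — the package's standard view of the
#' competition-colonization trade-off.
#'
#' @param object A [genotype_traits()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genotype_traits <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$fecundity_control, y = .data$seed_mass, colour = .data$group
    )
  ) +
    ggplot2::geom_point(size = 2, alpha = 0.85) +
    ggplot2::labs(
      x = "fecundity (fruits x mean fruit length, control)",
      y = "seed mass (mg/seed)", colour = "group"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an F_STQ / F_ST scan
#'
#' Ratio per trait (and cutoff when several were scanned); the dashed line at
#' 1 marks the neutral expectation.
#'
#' @param object An `fstq_result` tibble ([fstq_ratio()] / [fstq_scan()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fstq_result <- function(object, ...) {
  d <- dplyr::mutate(as_tibble(object),
    cutoff_lab = factor(sprintf("%.1f%%", 100 * .data$cutoff))
  )
  p <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data$trait, y = .data$ratio, fill = .data$cutoff_lab)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(
      x = NULL, y = expression(F[STQ] / F[ST]), fill = "top-SNP cutoff"
    ) +
    ggplot2::theme_minimal()
  if (length(unique(d$pair)) > 1) {
    p <- p + ggplot2::facet_wrap(~pair)
  }
  p
}

#' Plot outlier-haplotype enrichment
#'
#' Mean enrichment with +/- SEM error bars per biogeographical group,
#' faceted by effect sign (and trait when several are stacked); the dashed
#' line marks the null (0 in difference mode, 1 in ratio mode).
#'
#' @param object An `enrichment_result` tibble ([enrichment_bootstrap()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  d <- as_tibble(object)
  null_at <- if (d$mode[1] == "difference") 0 else 1
  p <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data$group, y = .data$enrichment, fill = .data$group)
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$enrichment - .data$sem, ymax = .data$enrichment + .data$sem
      ),
      width = 0.25
    ) +
    ggplot2::geom_hline(yintercept = null_at, linetype = 2) +
    ggplot2::labs(
      x = NULL,
      y = if (d$mode[1] == "difference") {
        "enrichment in outlier haplotypes (%)"
      } else {
        "proportion ratio (top / non-coding)"
      }
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (length(unique(d$trait)) > 1) {
    p + ggplot2::facet_grid(trait ~ sign)
  } else {
    p + ggplot2::facet_wrap(~sign)
  }
}

#' Plot S statistics and group deviations
#'
#' Group mean deviations from the estimated ancestral state for each trait
#' pair, annotated with the pair's S value — drift-only divergence gives S
#' near 0.5, directional selection pushes S toward 1.
#'
#' @param object An `s_statistic` tibble ([s_statistic()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.s_statistic <- function(object, ...) {
  dev <- attr(object, "deviations")
  labs <- dplyr::mutate(as_tibble(object),
    pair_lab = sprintf("%s vs %s (S = %.2f)", .data$trait1, .data$trait2, .data$S)
  )
  dev <- dplyr::left_join(
    dev, dplyr::select(labs, "trait1", "trait2", "pair_lab"),
    by = c("trait1", "trait2")
  )
  ggplot2::ggplot(dev, ggplot2::aes(x = .data$dev1, y = .data$dev2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2) +
    ggplot2::facet_wrap(~pair_lab, scales = "free") +
    ggplot2::labs(
      x = "deviation from ancestral mean (trait 1)",
      y = "deviation from ancestral mean (trait 2)", colour = "group"
    ) +
    ggplot2::theme_minimal()
}
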