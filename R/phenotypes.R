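#' Hampel outlier filter
#'
#' Robust outlier rule: a value is kept iff it lies within `k` raw median
#' absolute deviations of the group median (`MAD = median(|x - median(x)|)`,
#' unscaled — no normal-consistency factor). Intended to be applied within
#' genotype-by-treatment groups. Groups with fewer than 3 finite values pass
#' untouched; when the MAD is zero only values equal to the median survive and
#' a warning is emitted.
#'
#' @param x Numeric vector of measurements (one genotype-by-treatment group).
#' @param k MAD multiplier (default 3).
#' @return Logical keep mask the same length as `x` (`NA` values are dropped).
#' @export
#' @examples
#' hampel_filter(c(1, 2, 3, 4, 100)) # drops 100
hampel_filter <- function(x, k = 3) {
  keep <- !is.na(x)
  n <- sum(keep)
  if (n < 3) return(keep)
  med <- median(x[keep])
  mad0 <- median(abs(x[keep] - med))
  if (mad0 == 0) {
    warning("zero median absolute deviation: keeping only values equal to the median")
    return(keep & x == med)
  }
  keep & abs(x - med) <= k * mad0
}

# silent variant used in bulk processing (warning counts tracked by caller)
hampel_keep <- function(x, k = 3) {
  suppressWarnings(hampel_filter(x, k))
}

#' Fecundity proxy from fruit counts and mean fruit length
#'
#' Fecundity is estimated as the total fruit count multiplied by the mean
#' fruit length (mm), a proxy for the total number of seeds per plant.
#'
#' @param fruits Non-negative fruit count.
#' @param mean_fruit_length Mean fruit length in mm (from up to 4 sampled
#'   fruits); must be positive when `fruits > 0`.
#' @return Numeric fecundity score; `NA` (with a warning) when the length is
#'   missing but fruits were produced.
#' @export
#' @examples
#' derive_fecundity(100, 12) # 1200
derive_fecundity <- function(fruits, mean_fruit_length) {
  if (any(fruits < 0, na.rm = TRUE)) stop("fruit counts must be >= 0")
  bad <- fruits > 0 & (is.na(mean_fruit_length) | mean_fruit_length <= 0)
  if (any(bad, na.rm = TRUE)) {
    warning(sum(bad, na.rm = TRUE), " record(s) with fruits but no usable fruit length; returned NA")
  }
  out <- fruits * mean_fruit_length
  out[which(bad)] <- NA_real_
  out[which(fruits == 0)] <- 0
  out
}

#' Seed mass per seed from a weighed sample
#'
#' @param total_weight Total air-dried sample weight (mg).
#' @param n_seeds Number of seeds in the sample; samples outside 10-30 seeds
#'   trigger a warning, zero is an error.
#' @return Seed mass in mg/seed.
#' @export
#' @examples
#' derive_seed_mass(0.60, 30) # 0.02 mg/seed
derive_seed_mass <- function(total_weight, n_seeds) {
  if (any(n_seeds == 0, na.rm = TRUE)) stop("n_seeds must be positive")
  out_of_range <- n_seeds < 10 | n_seeds > 30
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sum(out_of_range, na.rm = TRUE), " seed sample(s) outside the 10-30 seed range")
  }
  total_weight / n_seeds
}

#' Fecundity response to a stress treatment
#'
#' Difference between a genotype's mean fecundity under stress (competition or
#' water limitation) and under control. The default is the signed difference
#' `stress - control` (declines are negative); `mode = "magnitude"` returns
#' the absolute difference. The convention used is recorded in the
#' `response_mode` attribute.
#'
#' @param mean_stress,mean_control Post-filter genotype mean fecundities.
#' @param mode `"signed"` (default) or `"magnitude"`.
#' @return Numeric response, `NA` where either arm is missing.
#' @export
#' @examples
#' stress_response(400, 1200) # -800
stress_response <- function(mean_stress, mean_control,
                            mode = c("signed", "magnitude")) {
  mode <- match.arg(mode)
  out <- mean_stress - mean_control
  if (mode == "magnitude") out <- abs(out)
  attr(out, "response_mode") <- mode
  out
}

#' Classify genotypes into biogeographical groups
#'
#' Combines geography and genetic ancestry: the area is south (`lat < 45`),
#' north (`lat > 55`) or center (in between; latitudes exactly at a threshold
#' are assigned to the center with a warning), and the genetic cluster is
#' relict iff more than 50% of the genome derives from the relict lineage.
#' The scheme has five groups — there is no "Center relict" group; that
#' combination errors unless `permissive = TRUE`.
#'
#' @param latitude Latitude in decimal degrees (finite).
#' @param relict_ancestry Genome-wide relict-ancestry fraction in \[0, 1\].
#' @param permissive Allow the "Center relict" combination (labelled as such)
#'   instead of erroring.
#' @return Factor with levels `North relict`, `North cosmopolitan`,
#'   `Center cosmopolitan`, `South cosmopolitan`, `South relict` (plus
#'   `Center relict` when permissive).
#' @export
#' @examples
#' classify_biogeo(40, 0.8) # South relict
classify_biogeo <- function(latitude, relict_ancestry, permissive = FALSE) {
  stopifnot(all(is.finite(latitude)), all(relict_ancestry >= 0 & relict_ancestry <= 1))
  at_threshold <- latitude == 45 | latitude == 55
  if (any(at_threshold)) {
    warning(sum(at_threshold), " latitude(s) exactly at a 45/55 threshold assigned to the center area")
  }
  area <- ifelse(latitude < 45, "South", ifelse(latitude > 55, "North", "Center"))
  cluster <- ifelse(relict_ancestry > 0.5, "relict", "cosmopolitan")
  label <- paste(area, cluster)
  bad <- label == "Center relict"
  if (any(bad) && !permissive) {
    stop(
      sum(bad), " genotype(s) classify as 'Center relict', which is not part of ",
      "the five-group scheme; set permissive = TRUE to allow it"
    )
  }
  levels <- c(
    "North relict", "North cosmopolitan", "Center cosmopolitan",
    "South cosmopolitan", "South relict"
  )
  if (permissive) levels <- c(levels, "Center relict")
  factor(label, levels = levels)
}

#' Genotype-level traits from individual plant records
#'
#' Turns raw plant records into filtered genotype means and derived traits.
#' Processing order: (1) drop plants that did not complete their life cycle;
#' (2) in the competition treatment, drop focal plants missing any of their
#' four neighbors; (3) derive plant-level fecundity (fruits x mean fruit
#' length) and seed mass (sample weight / seed count); (4) apply the Hampel
#' filter within genotype x treatment to fecundity, height and seed mass and
#' remove flagged records; (5) optionally remove block effects by centering
#' values on their block mean deviation within treatment; (6) average to
#' genotype means, compute stress responses, and attach the biogeographical
#' group from the metadata.
#'
#' A record-accounting audit (input = kept + incomplete + missing-neighbors +
#' Hampel-removed, per treatment) is attached as the `"audit"` attribute.
#'
#' @param plants Plant-record tibble (see [simulate_effects_and_traits()] for
#'   the schema).
#' @param metadata Genotype metadata with `genotype_id`, `latitude`,
#'   `relict_fraction`.
#' @param mad_k Hampel MAD multiplier.
#' @param response_mode Sign convention for stress responses, see
#'   [stress_response()].
#' @param block_center Remove block mean deviations before averaging.
#' @param min_neighbors Minimum neighbors for a competition record (default 4).
#' @param permissive Passed to [classify_biogeo()].
#' @return Tibble of class `genotype_traits`: one row per genotype with
#'   per-treatment mean fecundity, `seed_mass`, `height`, stress responses and
#'   `group`.
#' @export
genotype_traits <- function(plants, metadata, mad_k = 3,
                            response_mode = c("signed", "magnitude"),
                            block_center = TRUE, min_neighbors = 4,
                            permissive = FALSE) {
  response_mode <- match.arg(response_mode)
  treatments <- c("control", "competition", "water_stress")
  stopifnot(all(plants$treatment %in% treatments))

  d <- plants %>%
    dplyr::mutate(
      fecundity = suppressWarnings(derive_fecundity(.data$fruits, .data$fruit_length_mm)),
      seed_mass = ifelse(
        !is.na(.data$seed_count) & .data$seed_count > 0,
        .data$seed_weight_mg / .data$seed_count, NA_real_
      ),
      height = .data$height_cm,
      incomplete = !.data$complete_cycle | is.na(.data$fecundity),
      no_neighbors = .data$treatment == "competition" &
        (is.na(.data$neighbors_present) | .data$neighbors_present < min_neighbors)
    )

  audit_in <- dplyr::count(d, .data$treatment, name = "n_input")
  d1 <- dplyr::filter(d, !.data$incomplete)
  d2 <- dplyr::filter(d1, !.data$no_neighbors)

  d3 <- d2 %>%
    dplyr::group_by(.data$genotype_id, .data$treatment) %>%
    dplyr::mutate(
      keep = hampel_keep(.data$fecundity, mad_k) &
        (hampel_keep(.data$height, mad_k) | is.na(.data$height)) &
        (hampel_keep(.data$seed_mass, mad_k) | is.na(.data$seed_mass))
    ) %>%
    dplyr::ungroup()
  d4 <- dplyr::filter(d3, .data$keep)

  audit <- audit_in %>%
    dplyr::left_join(
      dplyr::count(d, .data$treatment, wt = .data$incomplete, name = "n_incomplete"),
      by = "treatment"
    ) %>%
    dplyr::left_join(
      dplyr::count(d1, .data$treatment, wt = .data$no_neighbors, name = "n_no_neighbors"),
      by = "treatment"
    ) %>%
    dplyr::left_join(
      dplyr::count(d3, .data$treatment, wt = !.data$keep, name = "n_hampel"),
      by = "treatment"
    ) %>%
    dplyr::left_join(dplyr::count(d4, .data$treatment, name = "n_kept"), by = "treatment") %>%
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_"), ~ tidyr::replace_na(.x, 0L)))

  if (block_center) {
    d4 <- d4 %>%
      dplyr::group_by(.data$treatment) %>%
      dplyr::mutate(dplyr::across(
        c("fecundity", "height", "seed_mass"),
        ~ .x - stats::ave(.x, paste(compartment, block), FUN = function(v) mean(v, na.rm = TRUE)) +
          mean(.x, na.rm = TRUE)
      )) %>%
      dplyr::ungroup()
  }

  means <- d4 %>%
    dplyr::group_by(.data$genotype_id, .data$treatment) %>%
    dplyr::summarise(
      fecundity = mean(.data$fecundity, na.rm = TRUE),
      height = mean(.data$height, na.rm = TRUE),
      seed_mass = mean(.data$seed_mass, na.rm = TRUE),
      .groups = "drop"
    )
  fec_wide <- means %>%
    dplyr::select("genotype_id", "treatment", "fecundity") %>%
    tidyr::pivot_wider(
      names_from = "treatment", values_from = "fecundity",
      names_prefix = "fecundity_"
    )
  for (cl in paste0("fecundity_", treatments)) {
    if (!cl %in% names(fec_wide)) fec_wide[[cl]] <- NA_real_
  }
  ctrl <- means %>%
    dplyr::filter(.data$treatment == "control") %>%
    dplyr::select("genotype_id", "seed_mass", "height")

  out <- fec_wide %>%
    dplyr::left_join(ctrl, by = "genotype_id") %>%
    dplyr::mutate(
      response_competition = as.numeric(stress_response(
        .data$fecundity_competition, .data$fecundity_control, response_mode
      )),
      response_water = as.numeric(stress_response(
        .data$fecundity_water_stress, .data$fecundity_control, response_mode
      ))
    ) %>%
    dplyr::left_join(
      dplyr::select(metadata, "genotype_id", "latitude", "relict_fraction"),
      by = "genotype_id"
    ) %>%
    dplyr::mutate(group = classify_biogeo(.data$latitude, .data$relict_fraction,
      permissive = permissive
    ))

  structure(
    out,
    class = c("genotype_traits", class(out)),
    audit = audit, response_mode = response_mode, mad_k = mad_k
  )
}

#' Broad-sense heritability by method-of-moments
#'
#' One-way random-effects ANOVA estimator with the unbalanced-design
#' correction: genotypic variance `sigma2_G = (MSB - MSW) / n0` (truncated at
#' zero and flagged when negative) and environmental variance
#' `sigma2_E = MSW`; `H2 = sigma2_G / (sigma2_G + sigma2_E)`.
#'
#' @param data Data frame of plant-level values.
#' @param value,genotype Unquoted column names of the trait value and the
#'   genotype identifier.
#' @return Object of class `variance_components` with elements `sigma2_G`,
#'   `sigma2_E`, `H2`, `truncated`, `n_genotypes`, `n_plants`.
#' @export
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 4), y = c(1, 1, 1, 1, 5, 5, 5, 5))
#' heritability(df, y, g)$H2
heritability <- function(data, value, genotype) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(genotype), data)
  comp <- anova_components(v, g)
  h2 <- if (comp$sigma2_B + comp$sigma2_W <= 0) NA_real_ else {
    comp$sigma2_B / (comp$sigma2_B + comp$sigma2_W)
  }
  structure(
    list(
      sigma2_G = comp$sigma2_B, sigma2_E = comp$sigma2_W, H2 = h2,
      truncated = comp$truncated, n_genotypes = comp$n_groups,
      n_plants = comp$n_total
    ),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> sigma2_G = %.4g, sigma2_E = %.4g, H2 = %.3f (%d genotypes, %d plants)%s\n",
    x$sigma2_G, x$sigma2_E, x$H2, x$n_genotypes, x$n_plants,
    if (x$truncated) " [negative genotypic component truncated at 0]" else ""
  ))
  invisible(x)
}

#' Label-shuffling null test for group trait means
#'
#' Compares each group's observed mean (over genotype means) to a null built
#' by randomly shuffling group labels across genotypes while keeping group
#' sizes fixed. Two-sided empirical p-values use the add-one correction
#' `(r + 1) / (n_reps + 1)` on the absolute deviation from the grand mean, so
#' p never reaches zero at finite replicates.
#'
#' @param traits Data frame of genotype means (e.g. [genotype_traits()]).
#' @param vars Character vector of trait columns to test.
#' @param group Unquoted grouping column (default `group`).
#' @param n_reps Number of label shuffles (default 100).
#' @param seed Optional seed for reproducible shuffles.
#' @return Tibble with one row per group x trait: `observed`, `null_mean`,
#'   `p`, `n_genotypes`. Null draws are kept in the `"null_draws"` attribute
#'   for plotting.
#' @export
null_group_test <- function(traits, vars, group = group, n_reps = 100, seed = NULL) {
  stopifnot(n_reps >= 1)
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), traits))
  keep_g <- !is.na(g)
  groups <- sort(unique(g[keep_g]))
  empty <- setdiff(unique(g), groups)
  if (length(empty)) warning("skipping empty group(s): ", paste(empty, collapse = ", "))
  with_seed(seed, {
    perms <- replicate(n_reps, sample(g[keep_g]))
    res <- purrr::map_dfr(vars, function(v) {
      x <- traits[[v]][keep_g]
      ok <- is.finite(x)
      centre <- mean(x[ok])
      obs <- tapply(x[ok], g[keep_g][ok], mean)
      nulls <- apply(perms, 2, function(lab) tapply(x[ok], lab[ok], mean))
      nulls <- nulls[names(obs), , drop = FALSE]
      purrr::map_dfr(names(obs), function(grp) {
        nv <- nulls[grp, ]
        tibble(
          trait = v, group = grp,
          observed = unname(obs[grp]),
          null_mean = mean(nv),
          p = (1 + sum(abs(nv - centre) >= abs(obs[grp] - centre))) / (n_reps + 1),
          n_genotypes = sum(g[keep_g][ok] == grp)
        )
      })
    })
    draws <- purrr::map_dfr(vars, function(v) {
      x <- traits[[v]][keep_g]
      ok <- is.finite(x)
      nulls <- apply(perms, 2, function(lab) tapply(x[ok], lab[ok], mean))
      tibble(
        trait = v,
        group = rep(rownames(nulls), ncol(nulls)),
        rep = rep(seq_len(ncol(nulls)), each = nrow(nulls)),
        value = as.vector(nulls)
      )
    })
    structure(res, null_draws = draws, n_reps = n_reps)
  })
}

#' Pairwise Pearson correlations between genotype-mean traits
#'
#' @param traits Data frame of genotype means.
#' @param vars Character vector of trait columns.
#' @return Tibble with one row per ordered pair (including the unit diagonal):
#'   `trait1`, `trait2`, `r`, `p`, `n`. The symmetric correlation matrix is
#'   attached as the `"matrix"` attribute. Zero-variance traits give `NA`
#'   entries with a warning.
#' @export
trait_correlations <- function(traits, vars) {
  stopifnot(length(vars) >= 1)
  x <- as.data.frame(traits[, vars])
  if (nrow(x) < 3) stop("need at least 3 genotypes")
  novar <- vapply(x, function(v) sd(v, na.rm = TRUE) == 0 || all(is.na(v)), logical(1))
  if (any(novar)) {
    warning("zero-variance trait(s): ", paste(vars[novar], collapse = ", "))
  }
  res <- purrr::map_dfr(seq_along(vars), function(i) {
    purrr::map_dfr(seq_along(vars), function(j) {
      if (i == j) {
        return(tibble(
          trait1 = vars[i], trait2 = vars[j], r = 1, p = NA_real_,
          n = sum(is.finite(x[[i]]))
        ))
      }
      ok <- is.finite(x[[i]]) & is.finite(x[[j]])
      if (novar[i] || novar[j] || sum(ok) < 3) {
        return(tibble(trait1 = vars[i], trait2 = vars[j], r = NA_real_, p = NA_real_, n = sum(ok)))
      }
      ct <- cor.test(x[[i]][ok], x[[j]][ok], method = "pearson")
      tibble(
        trait1 = vars[i], trait2 = vars[j],
        r = unname(ct$estimate), p = ct$p.value, n = sum(ok)
      )
    })
  })
  m <- matrix(res$r, length(vars), length(vars), dimnames = list(vars, vars))
  structure(res, matrix = m)
}
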