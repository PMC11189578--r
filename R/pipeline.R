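#' Analysis-stage parameters for the pipeline driver
#'
#' Collects every tunable of the downstream stages in one validated list;
#' unknown names are rejected so serialized configs cannot drift silently.
#'
#' @param mad_k Hampel MAD multiplier.
#' @param maf MAF filter threshold (strict).
#' @param ld_r2,ld_window_bp,ld_step LD pruning parameters.
#' @param qst_mode Q_ST denominator convention, see [qst()].
#' @param response_mode Stress-response sign convention.
#' @param cutoffs Top-SNP total fractions for the F_STQ scan.
#' @param top_fraction Top fraction for top-set outputs and enrichment.
#' @param n_perm,n_per_cat Enrichment bootstrap size.
#' @param n_boot Bootstrap replicates (Q_ST-F_ST test, ratio contrasts).
#' @param n_draws Monte-Carlo draws for the S statistic.
#' @param n_null Label-shuffling replicates for group null tests.
#' @param enrichment_mode `"difference"` or `"ratio"`.
#' @param stages Character vector of stages to run, in dependency order, from
#'   `simulate`, `phenotypes`, `popgen`, `polygenic`, `scan`.
#' @return List of class `pipeline_params`.
#' @export
pipeline_params <- function(mad_k = 3, maf = 0.05, ld_r2 = 0.1,
                            ld_window_bp = 50000, ld_step = 50,
                            qst_mode = "selfing", response_mode = "signed",
                            cutoffs = c(0.005, 0.01, 0.02, 0.05),
                            top_fraction = 0.01,
                            n_perm = 50, n_per_cat = 1000, n_boot = 1000,
                            n_draws = 1000, n_null = 100,
                            enrichment_mode = "difference",
                            stages = c("simulate", "phenotypes", "popgen", "polygenic", "scan")) {
  p <- list(
    mad_k = mad_k, maf = maf, ld_r2 = ld_r2, ld_window_bp = ld_window_bp,
    ld_step = ld_step, qst_mode = qst_mode, response_mode = response_mode,
    cutoffs = cutoffs, top_fraction = top_fraction, n_perm = n_perm,
    n_per_cat = n_per_cat, n_boot = n_boot, n_draws = n_draws,
    n_null = n_null, enrichment_mode = enrichment_mode, stages = stages
  )
  stopifnot(
    p$mad_k > 0, p$maf >= 0, p$maf < 0.5, p$ld_r2 > 0,
    all(p$stages %in% c("simulate", "phenotypes", "popgen", "polygenic", "scan"))
  )
  match.arg(p$qst_mode, c("selfing", "outcrossing"))
  match.arg(p$response_mode, c("signed", "magnitude"))
  match.arg(p$enrichment_mode, c("difference", "ratio"))
  structure(p, class = "pipeline_params")
}

#' Read pipeline parameters from a YAML config
#'
#' @param path YAML file with `pipeline_params()` fields (unknown keys are an
#'   error).
#' @return A [pipeline_params()] list.
#' @export
read_pipeline_params <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_params, vals)
}

traits_for_scan <- function() {
  c(
    "fecundity_control", "seed_mass", "height",
    "response_competition", "response_water"
  )
}

#' Run the full differentiation pipeline
#'
#' Executes the stages in dependency order — simulate, phenotypes, popgen,
#' polygenic, scan — writing every stage output as TSV under `out_dir` plus a
#' JSON run manifest (file checksums, record counts, warnings). Identical
#' config and seed give byte-identical outputs. A stage failure stops the run
#' after writing the partial manifest.
#'
#' @param config A [sim_config()] describing the simulated study (the
#'   `simulate` stage); its seed drives all stage-level randomness.
#' @param out_dir Output directory.
#' @param params A [pipeline_params()].
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         params = pipeline_params()) {
  stopifnot(inherits(config, "sim_config"), inherits(params, "pipeline_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- child_seed(config$seed, "pipeline")
  manifest <- list(
    package = "margindiff",
    version = as.character(utils::packageVersion("margindiff")),
    seed = config$seed, stages = list(), outputs = list(), warnings = character()
  )
  emit <- function(name, data) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(as_tibble(data), path)
    manifest$outputs[[name]] <<- list(
      file = basename(path), md5 = unname(tools::md5sum(path)),
      n_rows = nrow(data)
    )
    data
  }
  note <- function(...) {
    manifest$warnings <<- c(manifest$warnings, paste0(...))
  }
  finish <- function() {
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(
      list(
        sim_config = unclass(config)[!vapply(unclass(config), is.list, logical(1))],
        params = unclass(params)
      ),
      cfg_path
    )
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    jsonlite::write_json(
      manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  on.exit(finish())

  run <- function(stage) stage %in% params$stages
  fb <- traits <- g2 <- fst_all <- eff <- top_sets <- noncoding <- NULL

  if (run("simulate")) {
    fb <- simulate_study(config)
    write_fixture(fb, out_dir)
    manifest$stages$simulate <- list(
      n_genotypes = n_genotypes(fb$genotypes), n_snps = n_snps(fb$genotypes),
      n_plants = nrow(fb$plants)
    )
  } else {
    stop("run_pipeline currently requires the simulate stage (external inputs are read via read_genotypes and friends)")
  }

  if (run("phenotypes")) {
    traits <- withCallingHandlers(
      genotype_traits(fb$plants, fb$metadata,
        mad_k = params$mad_k, response_mode = params$response_mode
      ),
      warning = function(w) {
        note("phenotypes: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    emit("genotype_traits", traits)
    emit("filter_audit", attr(traits, "audit"))
    herit <- purrr::map_dfr(
      list(
        c("fecundity", "control"), c("height_cm", "control"),
        c("fecundity", "competition"), c("fecundity", "water_stress")
      ),
      function(item) {
        d <- dplyr::filter(fb$plants, .data$treatment == item[2], .data$complete_cycle)
        d$fecundity <- d$fruits * d$fruit_length_mm
        vc <- heritability(d, !!rlang::sym(item[1]), genotype_id)
        tibble(
          trait = item[1], treatment = item[2],
          sigma2_G = vc$sigma2_G, sigma2_E = vc$sigma2_E, H2 = vc$H2
        )
      }
    )
    emit("heritability", herit)
    emit("trait_correlations", trait_correlations(traits, traits_for_scan()))
    emit("group_null_tests", null_group_test(
      traits, traits_for_scan(),
      n_reps = params$n_null, seed = seed + 1L
    ))
    manifest$stages$phenotypes <- list(
      n_genotypes = nrow(traits),
      audit = as.list(colSums(attr(traits, "audit")[, -1]))
    )
  }

  if (run("popgen")) {
    g2 <- maf_filter(fb$genotypes, params$maf)
    pruned <- ld_prune(g2,
      r2_max = params$ld_r2, window_bp = params$ld_window_bp,
      step_snps = params$ld_step
    )
    emit("ld_pruned_snps", tibble(snp_id = pruned))
    grp <- setNames(as.character(traits$group), traits$genotype_id)
    fst_all <- wc_fst(g2, grp)
    emit("fst_all_groups", fst_all)
    fst_pairs <- wc_fst_pairs(g2, grp)
    emit("fst_pairs", fst_pairs)
    qsts <- purrr::map_dfr(traits_for_scan(), function(tr) {
      qt <- qst_fst_test(
        traits[[tr]], grp, fst_all,
        n_boot = params$n_boot,
        mode = params$qst_mode, seed = seed + 2L, trait = tr
      )
      tibble(
        trait = tr, qst = qt$qst, quantile = qt$quantile, p = qt$p,
        n_boot = qt$n_boot, mode = params$qst_mode
      )
    })
    emit("qst", qsts)
    theta <- coancestry_mom(g2, grp)
    emit(
      "coancestry",
      as_tibble(as.data.frame(unclass(theta)), rownames = "group")
    )
    gmat <- group_trait_means(traits, c("fecundity_control", "seed_mass", "height"))
    gcov <- within_group_cov(traits, c("fecundity_control", "seed_mass", "height"))
    svals <- s_statistic(gmat, theta, gcov,
      n_draws = params$n_draws, seed = seed + 3L
    )
    emit("s_statistic", svals)
    manifest$stages$popgen <- list(
      n_snps_maf = n_snps(g2), n_snps_pruned = length(pruned),
      fst_overall = unname(attr(fst_all, "fst_overall"))
    )
  }

  if (run("polygenic")) {
    eff <- combine_effects(fb$effects)
    emit("effects_combined", eff)
    top_sets <- purrr::map(
      setNames(sim_traits, sim_traits),
      function(tr) {
        select_top_snps(
          dplyr::filter(eff, .data$trait == tr),
          fraction = params$top_fraction, snps = fb$genotypes$snps, trait = tr
        )
      }
    )
    emit("top_snps", purrr::map_dfr(top_sets, function(ts) {
      tibble(
        trait = ts$trait,
        snp_id = c(ts$positive, ts$negative),
        tail = rep(c("positive", "negative"), c(length(ts$positive), length(ts$negative)))
      )
    }))
    corr <- dplyr::bind_rows(
      effect_correlations(eff, scope = "genome"),
      effect_correlations(eff, scope = "top", top_sets = top_sets)
    )
    emit("effect_correlations", corr)
    manifest$stages$polygenic <- list(
      n_top_per_trait = length(top_snp_ids(top_sets[[1]]))
    )
  }

  if (run("scan")) {
    noncoding <- g2$snps$snp_id[!g2$snps$coding]
    grp <- setNames(as.character(traits$group), traits$genotype_id)
    fst_pairs_tbl <- wc_fst_pairs(g2, grp)
    eff_traits <- setNames(sim_traits, traits_for_scan())
    scan_res <- withCallingHandlers(
      purrr::map_dfr(names(eff_traits), function(tr) {
        e1 <- dplyr::filter(eff, .data$trait == eff_traits[[tr]])
        purrr::map_dfr(unique(fst_pairs_tbl$pair), function(pr) {
          fstq_scan(
            dplyr::filter(fst_pairs_tbl, .data$pair == pr),
            e1, noncoding,
            cutoffs = params$cutoffs,
            snps = fb$genotypes$snps, trait = tr, skip_small = TRUE
          )
        })
      }),
      warning = function(w) {
        note("scan: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    emit("fstq_scan", scan_res)
    ref_groups <- levels(traits$group)[levels(traits$group) %in% traits$group]
    ref <- if ("South relict" %in% ref_groups) "South relict" else ref_groups[1]
    ref_pairs <- grep(ref, unique(fst_pairs_tbl$pair), value = TRUE, fixed = TRUE)
    if (length(ref_pairs) >= 2) {
      contrasts <- purrr::map_dfr(names(eff_traits), function(tr) {
        top <- select_top_snps(
          dplyr::filter(eff, .data$trait == eff_traits[[tr]]),
          fraction = params$top_fraction, snps = fb$genotypes$snps, trait = tr
        )
        sub <- dplyr::filter(fst_pairs_tbl, .data$pair %in% ref_pairs)
        tryCatch(
          dplyr::mutate(
            ratio_group_contrast(sub, top, noncoding,
              reference_pair = ref_pairs[1],
              n_boot = min(params$n_boot, 200), seed = seed + 4L
            ),
            trait = tr
          ),
          error = function(e) {
            note("scan contrast (", tr, "): ", conditionMessage(e))
            NULL
          }
        )
      })
      emit("fstq_group_contrasts", contrasts)
    }
    enrich <- purrr::map_dfr(names(eff_traits), function(tr) {
      top <- select_top_snps(
        dplyr::filter(eff, .data$trait == eff_traits[[tr]]),
        fraction = params$top_fraction, snps = fb$genotypes$snps, trait = tr
      )
      withCallingHandlers(
        enrichment_bootstrap(
          top, fb$ancestry, grp, noncoding, fb$genotypes$snps,
          n_perm = params$n_perm, n_per_cat = params$n_per_cat,
          mode = params$enrichment_mode, seed = seed + 5L
        ),
        warning = function(w) {
          note("scan: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
    })
    emit("enrichment", enrich)
    manifest$stages$scan <- list(
      n_pairs = length(unique(fst_pairs_tbl$pair)),
      n_noncoding = length(noncoding)
    )
  }

  invisible(manifest)
}
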