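# Synthetic study generator. The generator stages are deterministic functions
# of the config seed (via child_seed), so simulate_genomes() and
# simulate_ancestry_windows() reproduce the *same* ancestry mosaic
# independently, and simulate_effects_and_traits() re-derives the same causal
# architecture that shaped the lineage allele frequencies.

sim_traits <- c(
  "fecundity", "seed_mass", "height", "fecundity_competition", "fecundity_water"
)

# 10-kb windows tiling a genome; truncates (with a warning) if the genome
# length is not a multiple of the window size.
windows_tibble <- function(genome_length, window_bp = 10000L) {
  n_full <- genome_length %/% window_bp
  rem <- genome_length %% window_bp
  starts <- seq(0L, by = window_bp, length.out = n_full + (rem > 0))
  ends <- pmin(starts + window_bp, genome_length)
  if (rem > 0) {
    warning("genome length is not a multiple of the window size; last window truncated")
  }
  tibble(window = seq_along(starts), chrom = "1", start = starts, end = ends)
}

sim_metadata <- function(config) {
  areas <- c("south", "center", "north")
  n_area <- config$area_counts[areas]
  n_rel <- round(config$relict_fraction_by_area[areas] * n_area)
  lat_range <- list(
    south = c(37, 44.5), center = c(45.5, 54.5), north = c(55.5, 63)
  )
  with_seed(child_seed(config$seed, "metadata"), {
    md <- purrr::map_dfr(areas, function(a) {
      n <- n_area[[a]]
      if (n == 0L) return(NULL)
      tibble(
        area = a,
        cluster = rep(c("relict", "cosmopolitan"), c(n_rel[[a]], n - n_rel[[a]])),
        latitude = runif(n, lat_range[[a]][1], lat_range[[a]][2]),
        longitude = runif(n, -9, 27)
      )
    })
    md$genotype_id <- sprintf("g%03d", seq_len(nrow(md)))
    rng <- config$admixture_range
    md$relict_fraction <- ifelse(
      md$cluster == "relict",
      runif(nrow(md), rng$relict[1], rng$relict[2]),
      runif(nrow(md), rng$cosmopolitan[1], rng$cosmopolitan[2])
    )
    md[, c("genotype_id", "area", "cluster", "latitude", "longitude", "relict_fraction")]
  })
}

sim_snps <- function(config) {
  genome_length <- config$n_windows * 10000L
  with_seed(child_seed(config$seed, "genome"), {
    pos <- sort(sample.int(genome_length, config$n_snps)) - 1L # 0-based
    n_nc <- round(config$noncoding_fraction * config$n_snps)
    coding <- rep(TRUE, config$n_snps)
    coding[sample.int(config$n_snps, n_nc)] <- FALSE
    tibble(
      snp_id = sprintf("snp%05d", seq_len(config$n_snps)),
      chrom = "1", pos = pos, coding = coding,
      window = pos %/% 10000L + 1L
    )
  })
}

# Causal architecture: which coding SNPs carry effects, and per-trait effect
# sizes with the configured fecundity/seed-mass trade-off correlation.
sim_architecture <- function(config, snps) {
  coding_idx <- which(snps$coding)
  n_causal <- min(
    length(coding_idx),
    max(2L, ceiling(config$causal_fraction * config$n_snps))
  )
  with_seed(child_seed(config$seed, "architecture"), {
    causal_idx <- sort(sample(coding_idx, n_causal))
    rho <- config$tradeoff_rho
    sig <- matrix(c(1, rho, rho, 1), 2)
    z <- MASS::mvrnorm(n_causal, mu = c(0, 0), Sigma = sig)
    e_fec <- z[, 1]
    e_sm <- z[, 2]
    e_h <- 0.5 * e_fec + sqrt(1 - 0.25) * rnorm(n_causal)
    e_rc <- -0.45 * e_fec + sqrt(1 - 0.45^2) * rnorm(n_causal)
    e_rw <- -0.25 * e_fec + sqrt(1 - 0.25^2) * rnorm(n_causal)
    eff <- cbind(e_fec, e_sm, e_h, e_rc, e_rw)
    colnames(eff) <- sim_traits
    list(causal_idx = causal_idx, effects = eff)
  })
}

# Lineage allele frequencies: Balding-Nichols around a uniform ancestral
# frequency (straddling the 5% MAF cutoff); when the selection signal is on,
# causal SNPs get directionally divergent lineage frequencies keyed to the
# sign of their seed-mass effect (relicts enriched for seed-mass-increasing
# alleles, cosmopolitans for the alternative).
sim_frequencies <- function(config, snps, arch) {
  with_seed(child_seed(config$seed, "frequencies"), {
    p_anc <- runif(config$n_snps, 0.02, 0.98)
    f <- config$divergence_fst
    sh1 <- p_anc * (1 - f) / f
    sh2 <- (1 - p_anc) * (1 - f) / f
    p_rel <- rbeta(config$n_snps, sh1, sh2)
    p_cos <- rbeta(config$n_snps, sh1, sh2)
    if (config$selection_signal) {
      ci <- arch$causal_idx
      sm_pos <- arch$effects[, "seed_mass"] > 0
      n_pos <- sum(sm_pos)
      n_neg <- sum(!sm_pos)
      p_rel[ci[sm_pos]] <- rbeta(n_pos, 8, 2)
      p_cos[ci[sm_pos]] <- rbeta(n_pos, 2, 8)
      p_rel[ci[!sm_pos]] <- rbeta(n_neg, 2, 8)
      p_cos[ci[!sm_pos]] <- rbeta(n_neg, 8, 2)
    }
    p_rel <- pmin(pmax(p_rel, 0.005), 0.995)
    p_cos <- pmin(pmax(p_cos, 0.005), 0.995)
    list(p_anc = p_anc, p_rel = p_rel, p_cos = p_cos)
  })
}

# Binary relict/cosmopolitan status per genotype and 10-kb window. Base
# probability is the genotype's genome-wide relict fraction; when the
# enrichment signal is on, windows holding causal SNPs with positive seed-mass
# effects are pushed toward relict status in relict-cluster genotypes and away
# from it in cosmopolitans (and conversely for negative-effect windows).
sim_window_mosaic <- function(config, metadata, snps, arch) {
  n_g <- nrow(metadata)
  n_w <- config$n_windows
  q <- metadata$relict_fraction
  prob <- matrix(q, n_g, n_w)
  if (config$enrichment_signal) {
    ci <- arch$causal_idx
    sm <- arch$effects[, "seed_mass"]
    win_net <- tapply(sm, snps$window[ci], sum)
    win_pos <- as.integer(names(win_net))[win_net > 0]
    win_neg <- as.integer(names(win_net))[win_net < 0]
    # logit-scale shift: moves the relict-ancestry odds without letting the
    # minority ancestry take over, so window enrichment never cancels the
    # lineage allele-frequency divergence at causal SNPs
    shift <- 2 * config$enrichment_boost
    rel <- metadata$cluster == "relict"
    bump <- function(p, s) stats::plogis(stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)) + s) *
      (p > 0 & p < 1) + (p >= 1) # q = 0 or 1 stays pure
    prob[rel, win_pos] <- bump(q[rel], shift)
    prob[!rel, win_pos] <- bump(q[!rel], -shift)
    prob[rel, win_neg] <- bump(q[rel], -shift)
    prob[!rel, win_neg] <- bump(q[!rel], shift)
  }
  with_seed(child_seed(config$seed, "ancestry"), {
    w <- matrix(rbinom(n_g * n_w, 1L, prob), n_g, n_w)
    rownames(w) <- metadata$genotype_id
    w
  })
}

#' Simulate genotypes and genotype metadata
#'
#' Draws a haploid genotype matrix for an admixed panel of inbred lines. Two
#' ancestral lineages ("relict", "cosmopolitan") diverge under a
#' Balding-Nichols model with parameter `divergence_fst`; each genotype is a
#' mosaic of the two lineages over 10-kb windows, with its genome-wide relict
#' fraction recorded in the metadata. Latitudes populate all three areas
#' (south < 45, center 45-55, north > 55).
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `metadata` (tibble: `genotype_id`, `area`, `cluster`, `latitude`,
#'   `longitude`, `relict_fraction`).
#' @export
#' @examples
#' sim <- simulate_genomes(sim_config(n_snps = 200, seed = 1))
#' sim$genotypes
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_snps < 100) stop("simulate_genomes needs n_snps >= 100")
  metadata <- sim_metadata(config)
  if (!all(c("relict", "cosmopolitan") %in% metadata$cluster)) {
    stop("degenerate config: one ancestral cluster is empty; adjust relict_fraction_by_area")
  }
  snps <- sim_snps(config)
  arch <- sim_architecture(config, snps)
  freqs <- sim_frequencies(config, snps, arch)
  mosaic <- sim_window_mosaic(config, metadata, snps, arch)
  dosage <- with_seed(child_seed(config$seed, "dosage"), {
    p_use <- ifelse(
      mosaic[, snps$window, drop = FALSE] == 1L,
      matrix(freqs$p_rel, nrow(metadata), config$n_snps, byrow = TRUE),
      matrix(freqs$p_cos, nrow(metadata), config$n_snps, byrow = TRUE)
    )
    x <- matrix(
      rbinom(length(p_use), 1L, p_use), nrow(metadata), config$n_snps
    )
    if (config$missing_rate > 0) {
      x[runif(length(x)) < config$missing_rate] <- NA_integer_
    }
    rownames(x) <- metadata$genotype_id
    x
  })
  list(
    genotypes = genotype_matrix(dosage, snps[, c("snp_id", "chrom", "pos", "coding")]),
    metadata = metadata
  )
}

#' Simulate relict-ancestry status over 10-kb windows
#'
#' Reproduces, per genotype, the binary relict ("outlier-haplotype") status of
#' each 10-kb window used when drawing that genotype's mosaic in
#' [simulate_genomes()] (both derive the identical mosaic from the config
#' seed). The genotype-level mean window status matches the metadata relict
#' fraction up to sampling error.
#'
#' @param config The same [sim_config()] passed to [simulate_genomes()].
#' @param metadata The metadata tibble returned by [simulate_genomes()].
#' @return A BED-like tibble: `genotype_id`, `chrom`, `start`, `end` (0-based
#'   half-open) and `outlier` (0/1).
#' @export
simulate_ancestry_windows <- function(config, metadata) {
  stopifnot(inherits(config, "sim_config"))
  snps <- sim_snps(config)
  arch <- sim_architecture(config, snps)
  mosaic <- sim_window_mosaic(config, metadata, snps, arch)
  wins <- windows_tibble(config$n_windows * 10000L)
  out <- tidyr::crossing(genotype_id = metadata$genotype_id, wins) %>%
    dplyr::arrange(.data$genotype_id, .data$window)
  out$outlier <- as.integer(
    mosaic[cbind(match(out$genotype_id, rownames(mosaic)), out$window)]
  )
  dplyr::select(out, "genotype_id", "chrom", "start", "end", "outlier")
}

scale_to <- function(x, centre, spread, floor = -Inf) {
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) s <- 1
  pmax(centre + spread * (x - mean(x)) / s, floor)
}

#' Simulate SNP effect components and blocked greenhouse phenotypes
#'
#' Builds (i) a per-SNP, per-trait effect-component table in the sparse-model
#' decomposition `E = alpha + beta * delta` (small polygenic effect, sparse
#' large effect, inclusion probability), with causal fecundity and seed-mass
#' effects drawn at genetic correlation `tradeoff_rho`; and (ii) individual
#' plant records from the blocked greenhouse design (compartments, tables,
#' blocks), with residual noise calibrated so the method-of-moments
#' broad-sense heritability of each trait hits its `h2` target. Fecundity
#' under the competition and water-stress treatments subtracts a
#' genotype-specific penalty positively correlated with control fecundity, so
#' fecundity and stress response are non-independent, as in real panels.
#' Attrition, lost competition neighbors, and gross measurement outliers are
#' injected at the configured rates.
#'
#' @param config A [sim_config()].
#' @param genotypes The [genotype_matrix()] from [simulate_genomes()].
#' @param metadata The metadata tibble from [simulate_genomes()].
#' @return A list with `effects` (tibble: `snp_id`, `trait`, `alpha`, `beta`,
#'   `delta`), `plants` (tibble of plant records) and `truth` (generating
#'   parameters: group labels, genotype genetic values, causal SNP table, and
#'   realized among/within-group variance components per trait).
#' @export
simulate_effects_and_traits <- function(config, genotypes, metadata) {
  stopifnot(inherits(config, "sim_config"))
  snps <- sim_snps(config)
  arch <- sim_architecture(config, snps)
  n_snp <- config$n_snps
  n_g <- nrow(metadata)

  eff_tables <- with_seed(child_seed(config$seed, "effects"), {
    purrr::map(sim_traits, function(tr) {
      e_full <- numeric(n_snp)
      e_full[arch$causal_idx] <- arch$effects[, tr]
      noncausal <- setdiff(seq_len(n_snp), arch$causal_idx)
      e_full[noncausal] <- rnorm(length(noncausal), 0, 0.05)
      delta <- numeric(n_snp)
      alpha <- numeric(n_snp)
      beta <- numeric(n_snp)
      delta[arch$causal_idx] <- runif(length(arch$causal_idx), 0.6, 1)
      alpha[arch$causal_idx] <- e_full[arch$causal_idx] *
        runif(length(arch$causal_idx), 0, 0.2)
      beta[arch$causal_idx] <- (e_full[arch$causal_idx] - alpha[arch$causal_idx]) /
        delta[arch$causal_idx]
      delta[noncausal] <- runif(length(noncausal), 0, 0.05)
      alpha[noncausal] <- e_full[noncausal]
      tibble(
        snp_id = snps$snp_id, trait = tr,
        alpha = alpha, beta = beta, delta = delta
      )
    })
  })
  effects <- dplyr::bind_rows(eff_tables)

  # breeding values: dosage-weighted sums of total effects E = alpha + beta*delta
  x <- genotypes$dosage
  if (anyNA(x)) {
    freq <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- freq[idx[, 2]]
  }
  e_mat <- sapply(eff_tables, function(tb) tb$alpha + tb$beta * tb$delta)
  colnames(e_mat) <- sim_traits
  bv <- x %*% e_mat

  g_fec <- scale_to(bv[, "fecundity"], 2200, 800, floor = 50)
  g_sm <- scale_to(bv[, "seed_mass"], 0.020, 0.004, floor = 0.005)
  g_h <- scale_to(bv[, "height"], 30, 7, floor = 5)
  r_c <- scale_to(bv[, "fecundity_competition"], -0.55 * mean(g_fec), 450)
  r_w <- scale_to(bv[, "fecundity_water"], -0.35 * mean(g_fec), 350)
  g_fec_comp <- pmax(g_fec + r_c, 0.05 * g_fec)
  g_fec_water <- pmax(g_fec + r_w, 0.05 * g_fec)
  gvals <- cbind(
    fecundity = g_fec, seed_mass = g_sm, height = g_h,
    fecundity_competition = g_fec_comp, fecundity_water = g_fec_water
  )
  rownames(gvals) <- metadata$genotype_id

  h2 <- config$h2[sim_traits]
  env_var <- vapply(sim_traits, function(tr) {
    var(gvals[, tr]) * (1 - h2[[tr]]) / h2[[tr]]
  }, numeric(1))

  design <- tidyr::crossing(
    genotype_id = metadata$genotype_id,
    treatment = config$treatments,
    compartment = seq_len(config$compartments),
    block = seq_len(config$blocks_per_table)
  ) %>%
    dplyr::mutate(table = match(.data$treatment, config$treatments))
  n_rec <- nrow(design)

  plants <- with_seed(child_seed(config$seed, "traits"), {
    fec_context <- dplyr::case_when(
      design$treatment == config$treatments[1] ~ "fecundity",
      design$treatment == config$treatments[2] ~ "fecundity_competition",
      TRUE ~ "fecundity_water"
    )
    block_key <- paste(design$treatment, design$compartment, design$block)
    keys <- unique(block_key)
    mk_block <- function(s2) setNames(rnorm(length(keys), 0, sqrt(0.15 * s2)), keys)
    blk_fec <- sapply(
      c("fecundity", "fecundity_competition", "fecundity_water"),
      function(tr) mk_block(env_var[[tr]])
    )
    blk_h <- mk_block(env_var[["height"]])
    blk_sm <- mk_block(env_var[["seed_mass"]])

    gi <- design$genotype_id
    fec_g <- gvals[cbind(gi, fec_context)]
    fec_s2 <- env_var[fec_context]
    fec <- pmax(
      fec_g + blk_fec[cbind(block_key, fec_context)] +
        rnorm(n_rec, 0, sqrt(0.85 * fec_s2)),
      0
    )
    height <- pmax(
      gvals[gi, "height"] + blk_h[block_key] +
        rnorm(n_rec, 0, sqrt(0.85 * env_var[["height"]])),
      2
    )
    sm <- pmax(
      gvals[gi, "seed_mass"] + blk_sm[block_key] +
        rnorm(n_rec, 0, sqrt(0.85 * env_var[["seed_mass"]])),
      0.001
    )

    fruit_length <- pmax(rnorm(n_rec, 12, 1), 6)
    fruits <- pmax(round(fec / fruit_length), 0)
    if (config$outlier_rate > 0) {
      hit <- runif(n_rec) < config$outlier_rate
      fruits[hit] <- fruits[hit] * 8L + 200L
    }
    seed_count <- sample(10:30, n_rec, replace = TRUE)
    complete <- runif(n_rec) >= config$attrition_rate
    neighbors <- rep(NA_integer_, n_rec)
    comp <- design$treatment == config$treatments[2]
    lost <- comp & runif(n_rec) < config$neighbor_loss_rate
    neighbors[comp] <- 4L
    neighbors[lost] <- 4L - sample(1:3, sum(lost), replace = TRUE)

    tibble(
      plant_id = sprintf("p%05d", seq_len(n_rec)),
      genotype_id = gi,
      treatment = design$treatment,
      compartment = design$compartment,
      table = design$table,
      block = design$block,
      fruits = as.integer(fruits),
      fruit_length_mm = fruit_length,
      seed_count = as.integer(seed_count),
      seed_weight_mg = sm * seed_count,
      height_cm = height,
      complete_cycle = complete,
      neighbors_present = neighbors
    )
  })

  labels <- biogeo_label(metadata$area, metadata$cluster)
  gv_tbl <- as_tibble(gvals) %>%
    dplyr::mutate(
      genotype_id = metadata$genotype_id,
      response_competition = .data$fecundity_competition - .data$fecundity,
      response_water = .data$fecundity_water - .data$fecundity,
      .before = 1
    )
  sigma_tbl <- purrr::map_dfr(sim_traits, function(tr) {
    comp <- anova_components(gvals[, tr], labels)
    tibble(
      trait = tr, sigma2_B = comp$sigma2_B, sigma2_W = comp$sigma2_W,
      qst = comp$sigma2_B / (comp$sigma2_B + comp$sigma2_W)
    )
  })
  causal_tbl <- tidyr::crossing(
    tibble(
      snp_id = snps$snp_id[arch$causal_idx],
      idx = seq_along(arch$causal_idx)
    ),
    trait = sim_traits
  ) %>%
    dplyr::mutate(effect = arch$effects[cbind(
      .data$idx, match(.data$trait, colnames(arch$effects))
    )]) %>%
    dplyr::select("snp_id", "trait", "effect")

  truth <- list(
    group = setNames(labels, metadata$genotype_id),
    genotype_values = gv_tbl,
    variance_components = sigma_tbl,
    causal = causal_tbl,
    env_var = env_var,
    h2_target = h2
  )
  list(effects = effects, plants = plants, truth = truth)
}

# Map area x cluster to the five biogeographical labels used throughout.
biogeo_label <- function(area, cluster) {
  area_lab <- c(south = "South", center = "Center", north = "North")[area]
  paste(area_lab, ifelse(cluster == "relict", "relict", "cosmopolitan"))
}

#' Simulate a complete study fixture
#'
#' Runs all generator stages and bundles genotypes, metadata, ancestry
#' windows, effect components, plant records and the generating truth, so
#' every downstream operation (Q_ST recovery, enrichment nulls, S-statistic
#' regimes) can be scored against known parameters.
#'
#' @param config A [sim_config()].
#' @return A list of class `fixture_bundle` with elements `config`,
#'   `genotypes`, `metadata`, `ancestry`, `effects`, `plants`, `truth`.
#' @export
#' @examples
#' fb <- simulate_study(sim_config(n_snps = 200, seed = 7))
#' nrow(fb$plants)
simulate_study <- function(config = sim_config()) {
  gen <- simulate_genomes(config)
  ancestry <- simulate_ancestry_windows(config, gen$metadata)
  et <- simulate_effects_and_traits(config, gen$genotypes, gen$metadata)
  structure(
    list(
      config = config, genotypes = gen$genotypes, metadata = gen$metadata,
      ancestry = ancestry, effects = et$effects, plants = et$plants,
      truth = et$truth
    ),
    class = "fixture_bundle"
  )
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle>\n")
  print(x$genotypes)
  cat(sprintf(
    "  %d plant records, %d effect rows (%d traits), %d ancestry-window rows\n",
    nrow(x$plants), nrow(x$effects), length(unique(x$effects$trait)),
    nrow(x$ancestry)
  ))
  invisible(x)
}
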