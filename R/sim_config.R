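#' Configuration for the synthetic study generator
#'
#' Builds and validates the parameter set that drives [simulate_study()] and
#' its component generators. The defaults emulate the design of a 71-genotype
#' European *Arabidopsis thaliana* panel grown in a blocked greenhouse
#' experiment: three watering/competition treatments, each occupying one table
#' in each of two greenhouse compartments, four blocks per table, hence
#' 8 replicates per genotype and treatment and `71 * 8 * 3 = 1704` pots.
#'
#' Genotypes descend from two diverged ancestral lineages ("relict" and
#' "cosmopolitan") separated by a Balding-Nichols divergence of
#' `divergence_fst`, and each genotype is an inbred admixture mosaic of the two
#' lineages over 10-kb genomic windows. Latitudes place genotypes into south
#' (< 45), center (45-55) and north (> 55) areas, with relict-cluster
#' genotypes present only at the margins by default (7 of 24 in the south,
#' 11 of 24 in the north), mirroring the biogeography the analysis targets.
#'
#' @param n_genotypes Number of inbred genotypes (default 71).
#' @param n_snps Number of biallelic SNPs to simulate (>= 100).
#' @param n_windows Number of 10-kb genomic windows; the simulated genome is
#'   `n_windows * 10000` bp on a single chromosome.
#' @param divergence_fst Target neutral differentiation between the two
#'   ancestral lineages, in (0, 1). Realized Weir-Cockerham F_ST between
#'   pure-lineage genotypes matches this within sampling error.
#' @param area_counts Named integer vector: genotypes per area
#'   (`south`, `center`, `north`).
#' @param relict_fraction_by_area Named proportions of relict-cluster
#'   genotypes per area; counts are rounded deterministically.
#' @param admixture_range List with elements `relict` and `cosmopolitan`, each
#'   a length-2 range for the genome-wide relict-ancestry fraction drawn
#'   uniformly per genotype. Set to degenerate ranges (e.g. `c(1, 1)`) for
#'   pure-lineage genotypes.
#' @param noncoding_fraction Fraction of SNPs flagged non-coding (the neutral
#'   baseline set).
#' @param causal_fraction Fraction of SNPs (among coding SNPs) with nonzero
#'   trait effects.
#' @param tradeoff_rho Genetic correlation between fecundity and seed-mass SNP
#'   effects, in \[-1, 1\]; negative values encode the
#'   competition-colonization trade-off.
#' @param h2 Named broad-sense heritability targets in (0, 1) for
#'   `fecundity`, `seed_mass`, `height`, `fecundity_competition`,
#'   `fecundity_water`.
#' @param replicates Replicates per genotype and treatment; must equal
#'   `blocks_per_table * compartments`.
#' @param treatments Treatment labels; one treatment per table per compartment,
#'   so `length(treatments)` must equal `tables_per_compartment`.
#' @param compartments,tables_per_compartment,blocks_per_table Greenhouse
#'   nesting structure.
#' @param attrition_rate Probability a plant fails to complete its life cycle.
#' @param outlier_rate Probability a plant record receives a gross measurement
#'   error (exercises the Hampel filter).
#' @param neighbor_loss_rate Probability a competition pot loses one or more of
#'   its four neighbor plants.
#' @param missing_rate Per-call genotype missingness rate.
#' @param selection_signal If `TRUE`, causal-SNP lineage frequencies are drawn
#'   divergently (relicts enriched for alleles increasing seed mass, depleted
#'   for alleles increasing fecundity), creating directional-selection
#'   signatures. If `FALSE` all SNPs are neutral-equivalent.
#' @param enrichment_signal If `TRUE`, ancestry windows overlapping causal
#'   SNPs with positive seed-mass effects are enriched in relict status for
#'   relict-cluster genotypes (and depleted for cosmopolitans), so
#'   outlier-haplotype enrichment is detectable.
#' @param enrichment_boost Strength of the window-level enrichment in (0, 1).
#' @param seed Integer random seed; all stage-level randomness is derived
#'   deterministically from it.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_study()]
#' @export
#' @examples
#' cfg <- sim_config(n_snps = 500, seed = 1)
#' cfg$n_genotypes
sim_config <- function(n_genotypes = 71,
                       n_snps = 2000,
                       n_windows = 100,
                       divergence_fst = 0.3,
                       area_counts = c(south = 24, center = 23, north = 24),
                       relict_fraction_by_area = c(south = 7 / 24, center = 0, north = 11 / 24),
                       admixture_range = list(
                         relict = c(0.75, 0.98),
                         cosmopolitan = c(0.02, 0.25)
                       ),
                       noncoding_fraction = 0.4,
                       causal_fraction = 0.02,
                       tradeoff_rho = -0.6,
                       h2 = c(
                         fecundity = 0.55, seed_mass = 0.63, height = 0.50,
                         fecundity_competition = 0.40, fecundity_water = 0.45
                       ),
                       replicates = 8,
                       treatments = c("control", "competition", "water_stress"),
                       compartments = 2,
                       tables_per_compartment = 3,
                       blocks_per_table = 4,
                       attrition_rate = 0,
                       outlier_rate = 0,
                       neighbor_loss_rate = 0,
                       missing_rate = 0,
                       selection_signal = TRUE,
                       enrichment_signal = TRUE,
                       enrichment_boost = 0.5,
                       seed = 1) {
  cfg <- list(
    n_genotypes = as.integer(n_genotypes), n_snps = as.integer(n_snps),
    n_windows = as.integer(n_windows), divergence_fst = divergence_fst,
    area_counts = area_counts, relict_fraction_by_area = relict_fraction_by_area,
    admixture_range = admixture_range, noncoding_fraction = noncoding_fraction,
    causal_fraction = causal_fraction, tradeoff_rho = tradeoff_rho, h2 = h2,
    replicates = as.integer(replicates), treatments = treatments,
    compartments = as.integer(compartments),
    tables_per_compartment = as.integer(tables_per_compartment),
    blocks_per_table = as.integer(blocks_per_table),
    attrition_rate = attrition_rate, outlier_rate = outlier_rate,
    neighbor_loss_rate = neighbor_loss_rate, missing_rate = missing_rate,
    selection_signal = isTRUE(selection_signal),
    enrichment_signal = isTRUE(enrichment_signal),
    enrichment_boost = enrichment_boost, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_genotypes >= 2, cfg$n_snps >= 1, cfg$n_windows >= 1,
    length(cfg$treatments) >= 1
  )
  if (cfg$divergence_fst <= 0 || cfg$divergence_fst >= 1) {
    stop("divergence_fst must lie strictly in (0, 1)")
  }
  props <- c(
    cfg$relict_fraction_by_area, cfg$noncoding_fraction, cfg$causal_fraction,
    cfg$attrition_rate, cfg$outlier_rate, cfg$neighbor_loss_rate,
    cfg$missing_rate, cfg$enrichment_boost,
    unlist(cfg$admixture_range)
  )
  if (any(props < 0 | props > 1)) stop("all proportions must lie in [0, 1]")
  if (abs(cfg$tradeoff_rho) > 1) stop("tradeoff_rho must lie in [-1, 1]")
  if (any(cfg$h2 <= 0) || any(cfg$h2 >= 1)) {
    stop("heritability targets h2 must lie strictly in (0, 1); h2 >= 1 is unattainable")
  }
  if (!setequal(names(cfg$area_counts), c("south", "center", "north")) ||
      !setequal(names(cfg$relict_fraction_by_area), c("south", "center", "north"))) {
    stop("area_counts and relict_fraction_by_area need names south, center, north")
  }
  if (sum(cfg$area_counts) != cfg$n_genotypes) {
    stop("area_counts must sum to n_genotypes")
  }
  if (cfg$replicates != cfg$blocks_per_table * cfg$compartments) {
    stop("replicates must equal blocks_per_table * compartments")
  }
  if (length(cfg$treatments) != cfg$tables_per_compartment) {
    stop("one treatment per table: length(treatments) must equal tables_per_compartment")
  }
  if (cfg$n_snps > cfg$n_windows * 10000L) {
    stop("n_snps exceeds the number of available genomic positions")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d genotypes, %d SNPs over %d x 10-kb windows, lineage F_ST %.2f\n",
    x$n_genotypes, x$n_snps, x$n_windows, x$divergence_fst
  ))
  cat(sprintf(
    "  design: %d treatments x %d replicates (%d compartments x %d blocks) = %d records\n",
    length(x$treatments), x$replicates, x$compartments, x$blocks_per_table,
    x$n_genotypes * length(x$treatments) * x$replicates
  ))
  cat(sprintf(
    "  signals: selection=%s enrichment=%s; seed %d\n",
    x$selection_signal, x$enrichment_signal, x$seed
  ))
  invisible(x)
}
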