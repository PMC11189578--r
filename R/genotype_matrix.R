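#' Genotype matrix container for inbred lines
#'
#' A light container pairing a haploid dosage matrix (genotypes x SNPs, values
#' 0/1/`NA`) with a SNP annotation tibble. Inbred selfing lines are effectively
#' homozygous, so each line carries a single allele per site and dosages are
#' coded 0/1; diploid heterozygotes are not represented (they become missing
#' at the VCF boundary, see [read_genotypes()]).
#'
#' Positions are 0-based half-open internally; they become 1-based only when
#' written to or read from VCF.
#'
#' @param dosage Integer matrix, genotypes in rows, SNPs in columns, entries
#'   in `{0, 1, NA}`. Row names are genotype ids.
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos` (0-based) and
#'   logical `coding`; one row per dosage column.
#' @return An object of class `genotype_matrix`.
#' @export
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c(0L, 1L, 1L, 0L), 2, 2, dimnames = list(c("g1", "g2"), NULL)),
#'   tibble::tibble(snp_id = c("s1", "s2"), chrom = "1", pos = c(0L, 100L),
#'                  coding = c(TRUE, FALSE))
#' )
#' n_snps(gm)
genotype_matrix <- function(dosage, snps) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  snps <- as_tibble(snps)
  stopifnot(
    ncol(dosage) == nrow(snps),
    all(c("snp_id", "chrom", "pos", "coding") %in% names(snps))
  )
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0L, 1L))) {
    stop("dosages must be 0, 1 or NA (biallelic inbred lines)")
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("g%03d", seq_len(nrow(dosage)))
  }
  if (anyDuplicated(snps$snp_id)) stop("duplicated snp_id")
  colnames(dosage) <- snps$snp_id
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' @rdname genotype_matrix
#' @param g A `genotype_matrix`.
#' @export
n_snps <- function(g) ncol(g$dosage)

#' @rdname genotype_matrix
#' @export
n_genotypes <- function(g) nrow(g$dosage)

#' @rdname genotype_matrix
#' @export
genotype_ids <- function(g) rownames(g$dosage)

#' Alternate-allele frequencies per SNP
#'
#' @param g A `genotype_matrix`.
#' @return Named numeric vector of allele-1 frequencies from non-missing calls.
#' @export
allele_freq <- function(g) colMeans(g$dosage, na.rm = TRUE)

#' Subset a genotype matrix by SNP id
#'
#' @param g A `genotype_matrix`.
#' @param keep Character vector of `snp_id`s (order preserved as in `g`).
#' @return A `genotype_matrix` restricted to the kept SNPs.
#' @export
subset_snps <- function(g, keep) {
  idx <- which(g$snps$snp_id %in% keep)
  if (!length(idx)) stop("no SNPs left after subsetting")
  genotype_matrix(g$dosage[, idx, drop = FALSE], g$snps[idx, ])
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d genotypes x %d SNPs (%d non-coding), %.2f%% missing\n",
    n_genotypes(x), n_snps(x), sum(!x$snps$coding),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}
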