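# File formats. TSV is the interchange format between stages; VCF only at the
# genotype boundary; BED-like 0-based half-open tables for ancestry windows.

#' Write a genotype matrix as a plain-text haploid VCF
#'
#' GT-only biallelic VCF 4.2 with haploid calls (`0`, `1`, `.`); the internal
#' 0-based positions become 1-based in the file, and the coding flag is kept
#' in the INFO field (`CODING=0/1`).
#'
#' @param g A [genotype_matrix()].
#' @param path Output path (plain text, not compressed).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(g, path) {
  snps <- g$snps
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=margindiff",
    "##INFO=<ID=CODING,Number=1,Type=Integer,Description=\"1 if the SNP is in a coding region\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste0("##contig=<ID=", paste(unique(snps$chrom)), ">"),
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      genotype_ids(g)
    ), collapse = "\t")
  )
  gt <- t(g$dosage)
  gt_chr <- matrix(as.character(gt), nrow(gt), ncol(gt))
  gt_chr[is.na(gt)] <- "."
  body <- paste(
    snps$chrom, snps$pos + 1L, snps$snp_id, "A", "T", ".", "PASS",
    paste0("CODING=", as.integer(snps$coding)), "GT",
    apply(gt_chr, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from VCF or a dosage TSV
#'
#' VCF: biallelic records with haploid (`0`/`1`) or homozygous-diploid
#' (`0/0`, `1/1`) GT calls become dosages 0/1; heterozygous calls become
#' missing with a warning count; multiallelic records are skipped and
#' counted; 1-based VCF positions become 0-based internally. A `CODING` INFO
#' flag is honoured (SNPs default to coding when absent). Dosage TSV: the
#' format written by [write_dosage_tsv()].
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  }
  if (format == "dosage") {
    return(read_dosage_tsv(path))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "") | is.na(fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt_raw <- gt_raw[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (!nrow(fix)) stop("no biallelic records in ", path)
  clean <- gsub("\\|", "/", gt_raw)
  dos <- matrix(NA_integer_, nrow(clean), ncol(clean))
  dos[clean %in% c("0", "0/0")] <- 0L
  dos[clean %in% c("1", "1/1")] <- 1L
  het <- clean %in% c("0/1", "1/0")
  if (any(het)) {
    warning(sum(het), " heterozygous call(s) set to missing (inbred-line coding)")
  }
  coding <- rep(TRUE, nrow(fix))
  info <- fix$INFO %||% rep(NA_character_, nrow(fix))
  has_flag <- grepl("CODING=", info)
  coding[has_flag] <- sub(".*CODING=([01]).*", "\\1", info[has_flag]) == "1"
  snps <- tibble(
    snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
      paste0(fix$CHROM, ":", fix$POS), fix$ID
    ),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    coding = coding
  )
  dosage <- t(dos)
  rownames(dosage) <- colnames(gt_raw)
  genotype_matrix(dosage, snps)
}

#' Dosage-table round trip
#'
#' Plain TSV with SNP annotation columns (`snp_id`, `chrom`, `pos`, `coding`)
#' followed by one 0/1/NA column per genotype.
#'
#' @param g A [genotype_matrix()].
#' @param path File path.
#' @return `write_dosage_tsv()`: `path` invisibly; `read_dosage_tsv()`: a
#'   [genotype_matrix()].
#' @export
write_dosage_tsv <- function(g, path) {
  tab <- dplyr::bind_cols(
    g$snps[, c("snp_id", "chrom", "pos", "coding")],
    as_tibble(t(g$dosage))
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  anno <- c("snp_id", "chrom", "pos", "coding")
  stopifnot(all(anno %in% names(tab)))
  ids <- setdiff(names(tab), anno)
  dosage <- t(as.matrix(tab[, ids]))
  rownames(dosage) <- ids
  genotype_matrix(
    dosage,
    dplyr::mutate(tab[, anno], chrom = as.character(.data$chrom))
  )
}

#' Write all files of a simulated study fixture
#'
#' Writes the fixture's genotypes (VCF), metadata, effects, ancestry windows
#' and plant records (TSV) plus a truth manifest (JSON) into a directory.
#'
#' @param bundle A `fixture_bundle` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.vcf"),
    metadata = file.path(dir, "metadata.tsv"),
    effects = file.path(dir, "effects.tsv"),
    ancestry = file.path(dir, "ancestry_windows.tsv"),
    plants = file.path(dir, "plants.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_genotypes_vcf(bundle$genotypes, paths["genotypes"])
  readr::write_tsv(bundle$metadata, paths["metadata"])
  readr::write_tsv(bundle$effects, paths["effects"])
  readr::write_tsv(bundle$ancestry, paths["ancestry"])
  readr::write_tsv(bundle$plants, paths["plants"])
  truth <- bundle$truth
  truth$group <- as.list(setNames(as.character(truth$group), names(truth$group)))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
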