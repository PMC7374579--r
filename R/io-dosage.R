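# Dosage TSV triplet: <path> (genotype counts), <path>.snps.tsv (SNP
# metadata), <path>.pheno.tsv (phenotype).

#' Read the dosage TSV triplet
#'
#' The dosage dialect is three tab-separated files sharing a path prefix:
#' \describe{
#'   \item{`path`}{header `subject_id<TAB>snp1<TAB>...`, one row per subject,
#'     entries in `{0, 1, 2, NA}` (allele counts).}
#'   \item{`<path>.snps.tsv`}{columns `snp_id`, `chrom`, `pos`, `ref`, `alt`.}
#'   \item{`<path>.pheno.tsv`}{columns `subject_id`, `diagnosis`,
#'     `apoe_e4_count`.}
#' }
#' `NA` entries become missing genotypes. Orientation is normalised on load so
#' the counted allele is the observed minor allele (see
#' [normalize_orientation()]).
#'
#' @param path path of the main genotype TSV.
#' @return a [genotype_dataset()].
#' @export
read_dosage_tsv <- function(path) {
  geno <- read_tsv_file(path)
  if (names(geno)[1] != "subject_id") {
    stop_format("%s: first column must be subject_id", path)
  }
  snps <- read_tsv_file(paste0(path, ".snps.tsv"))
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(snps))) {
    stop_format("%s.snps.tsv must have columns %s", path,
                paste(need, collapse = ", "))
  }
  snp_ids <- names(geno)[-1]
  if (!identical(as.character(snps$snp_id), snp_ids)) {
    stop_format("%s: header SNPs disagree with companion .snps.tsv", path)
  }
  G <- as.matrix(geno[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  raw <- unlist(geno[, -1, drop = FALSE], use.names = FALSE)
  bad <- !is.na(raw) & !(raw %in% c(0, 1, 2, "0", "1", "2"))
  if (any(bad)) {
    stop_format("%s: genotype entry outside {0,1,2,NA}: '%s'", path,
                as.character(raw[bad][1]))
  }
  dimnames(G) <- NULL

  pheno <- read_tsv_file(paste0(path, ".pheno.tsv"))
  need <- c("subject_id", "diagnosis", "apoe_e4_count")
  if (!all(need %in% names(pheno))) {
    stop_format("%s.pheno.tsv must have columns %s", path,
                paste(need, collapse = ", "))
  }
  subject_ids <- as.character(geno$subject_id)
  idx <- match(subject_ids, as.character(pheno$subject_id))
  if (anyNA(idx)) {
    stop_format("%s: subject %s missing from companion .pheno.tsv", path,
                subject_ids[is.na(idx)][1])
  }
  phenotype <- data.frame(
    subject_id = subject_ids,
    diagnosis = as.character(pheno$diagnosis[idx]),
    apoe_e4_count = as.integer(pheno$apoe_e4_count[idx]),
    stringsAsFactors = FALSE)

  ds <- genotype_dataset(subject_ids, snp_ids,
                         chrom = as.character(snps$chrom),
                         pos = as.integer(snps$pos),
                         alleles = cbind(as.character(snps$ref),
                                         as.character(snps$alt)),
                         G = G, phenotype = phenotype)
  normalize_orientation(ds)
}

#' Write the dosage TSV triplet
#'
#' Inverse of [read_dosage_tsv()]; writes the three files deterministically
#' (UTF-8, tab-separated, fixed column order).
#'
#' @param ds a [genotype_dataset()].
#' @param path path of the main genotype TSV; companions get `.snps.tsv` and
#'   `.pheno.tsv` suffixes.
#' @return invisibly, `path`.
#' @export
write_dosage_tsv <- function(ds, path) {
  geno <- data.frame(subject_id = ds$subject_ids, stringsAsFactors = FALSE)
  gm <- as.data.frame(ds$G)
  names(gm) <- ds$snp_ids
  geno <- cbind(geno, gm)
  write_tsv_file(geno, path)
  snps <- data.frame(snp_id = ds$snp_ids, chrom = ds$chrom, pos = ds$pos,
                     ref = ds$alleles[, 1], alt = ds$alleles[, 2])
  write_tsv_file(snps, paste0(path, ".snps.tsv"))
  write_tsv_file(ds$phenotype, paste0(path, ".pheno.tsv"))
  invisible(path)
}
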