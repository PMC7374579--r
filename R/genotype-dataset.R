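#' Construct a genotype dataset
#'
#' The central container of the package: a subjects-by-SNPs matrix of
#' minor-allele counts together with SNP metadata and a per-subject phenotype
#' table. All analysis stages consume this object (directly or through
#' [encode_genotypes()]).
#'
#' @param subject_ids character vector of unique subject identifiers.
#' @param snp_ids character vector of unique SNP identifiers.
#' @param chrom per-SNP chromosome label (character, e.g. `"1"`..`"22"`, `"X"`).
#' @param pos per-SNP 1-based base-pair position (integer, >= 1).
#' @param alleles two-column character matrix; column 1 is the major (reference)
#'   allele, column 2 the minor (counted) allele.
#' @param G integer matrix, subjects x SNPs, entries in `{0, 1, 2}` counting
#'   minor alleles, with `NA` for missing calls.
#' @param phenotype data frame with columns `subject_id`, `diagnosis`
#'   (`"case"`/`"control"`, or `NA`) and `apoe_e4_count` (0/1/2 or `NA`).
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(subject_ids, snp_ids, chrom, pos, alleles, G,
                             phenotype) {
  ds <- structure(
    list(subject_ids = as.character(subject_ids),
         snp_ids = as.character(snp_ids),
         chrom = as.character(chrom),
         pos = as.integer(pos),
         alleles = alleles,
         G = G,
         phenotype = phenotype),
    class = "genotype_dataset")
  validate_genotype_dataset(ds)
  ds
}

#' Validate genotype-dataset invariants
#'
#' Checks identifier uniqueness, dimension agreement, genotype range and
#' position sanity; stops with an informative error on the first violation.
#'
#' @param ds a [genotype_dataset()].
#' @return `ds`, invisibly.
#' @export
validate_genotype_dataset <- function(ds) {
  if (anyDuplicated(ds$subject_ids)) stop_format("duplicate subject_ids")
  if (anyDuplicated(ds$snp_ids)) stop_format("duplicate snp_ids")
  if (nrow(ds$G) != length(ds$subject_ids)) {
    stop_format("G has %d rows but %d subject_ids", nrow(ds$G),
                length(ds$subject_ids))
  }
  p <- length(ds$snp_ids)
  if (ncol(ds$G) != p || length(ds$chrom) != p || length(ds$pos) != p ||
      nrow(ds$alleles) != p) {
    stop_format("SNP metadata lengths disagree with ncol(G) = %d", ncol(ds$G))
  }
  g <- ds$G[!is.na(ds$G)]
  if (length(g) && !all(g %in% 0:2)) {
    stop_format("non-missing genotypes outside {0,1,2}")
  }
  if (any(ds$pos < 1L, na.rm = TRUE)) stop_format("positions must be >= 1")
  ph <- ds$phenotype
  need <- c("subject_id", "diagnosis", "apoe_e4_count")
  if (!all(need %in% names(ph))) {
    stop_format("phenotype table must have columns %s",
                paste(need, collapse = ", "))
  }
  if (!identical(as.character(ph$subject_id), ds$subject_ids)) {
    stop_format("phenotype subject_id must match subject_ids in order")
  }
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n_miss <- sum(is.na(x$G))
  cat(sprintf("genotype_dataset: %d subjects x %d SNPs on %d chromosome(s)\n",
              length(x$subject_ids), length(x$snp_ids),
              length(unique(x$chrom))))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", n_miss,
              100 * n_miss / length(x$G)))
  cat(sprintf("  cases/controls: %d/%d\n",
              sum(x$phenotype$diagnosis == "case", na.rm = TRUE),
              sum(x$phenotype$diagnosis == "control", na.rm = TRUE)))
  invisible(x)
}

#' Minor-allele frequency per SNP
#'
#' Computed from non-missing calls only: `MAF_j = mean(G[, j]) / 2`. After
#' orientation normalisation (see [normalize_orientation()]) values lie in
#' `[0, 0.5]`.
#'
#' @param ds a [genotype_dataset()].
#' @return named numeric vector of per-SNP frequencies.
#' @export
snp_maf <- function(ds) {
  maf <- colMeans(ds$G, na.rm = TRUE) / 2
  maf[is.nan(maf)] <- 0
  names(maf) <- ds$snp_ids
  maf
}

#' Force minor-allele orientation of the genotype coding
#'
#' Recomputes the frequency of the counted allele from the observed data; any
#' SNP whose counted allele has frequency above 0.5 is flipped (`g -> 2 - g`,
#' alleles swapped). Exact ties at 0.5 are resolved so that the counted allele
#' is the alphabetically earlier of the two. Readers apply this so that the
#' minor-allele coding is a property of the data, not of input metadata.
#'
#' @param ds a [genotype_dataset()].
#' @return a [genotype_dataset()] with every counted-allele frequency <= 0.5.
#' @export
normalize_orientation <- function(ds) {
  freq <- colMeans(ds$G, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- 0
  flip <- freq > 0.5
  tie <- !is.na(freq) & freq == 0.5
  if (any(tie)) {
    # counted allele (col 2) must sort before the other at an exact tie
    flip[tie] <- ds$alleles[tie, 2] > ds$alleles[tie, 1]
  }
  if (any(flip)) {
    ds$G[, flip] <- 2L - ds$G[, flip]
    ds$alleles[flip, ] <- ds$alleles[flip, 2:1]
  }
  ds
}

#' Restrict a dataset to a subset of subjects and/or SNPs
#'
#' @param ds a [genotype_dataset()].
#' @param subjects character vector of subject ids to keep (original order is
#'   preserved); `NULL` keeps all.
#' @param snps character vector of SNP ids to keep; `NULL` keeps all.
#' @return the restricted [genotype_dataset()].
#' @export
subset_dataset <- function(ds, subjects = NULL, snps = NULL) {
  keep_s <- if (is.null(subjects)) rep(TRUE, length(ds$subject_ids)) else
    ds$subject_ids %in% subjects
  keep_j <- if (is.null(snps)) rep(TRUE, length(ds$snp_ids)) else
    ds$snp_ids %in% snps
  genotype_dataset(
    subject_ids = ds$subject_ids[keep_s],
    snp_ids = ds$snp_ids[keep_j],
    chrom = ds$chrom[keep_j],
    pos = ds$pos[keep_j],
    alleles = ds$alleles[keep_j, , drop = FALSE],
    G = ds$G[keep_s, keep_j, drop = FALSE],
    phenotype = ds$phenotype[keep_s, , drop = FALSE])
}
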