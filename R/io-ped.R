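# PLINK text PED/MAP reader and writer.

#' Read a PLINK text PED/MAP pair
#'
#' Parses the classic whitespace-delimited PLINK text format: the MAP file has
#' one row per SNP (`chrom`, `snp_id`, genetic distance, `pos`); the PED file
#' has one row per subject with six leading columns (family id, subject id,
#' paternal id, maternal id, sex, phenotype) followed by two allele characters
#' per SNP. Allele characters must be in `A, C, G, T`; `0` marks a missing
#' call (`"0 0"` pairs become missing genotypes and are excluded from allele
#' frequency computation).
#'
#' Genotypes are coded as minor-allele counts, with the minor allele determined
#' from the observed frequencies (ties at 0.5 broken by alphabetical order).
#' PED column 6 fills the diagnosis (1 = control, 2 = case, anything else
#' missing). The APOE e4 allele count is not part of the PED format; supply it
#' through `pheno_path`, a TSV with columns `subject_id`, `apoe_e4_count`
#' (and optionally `diagnosis`, which then overrides PED column 6).
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @param pheno_path optional sidecar phenotype TSV (see above).
#' @return a [genotype_dataset()] in minor-allele orientation.
#' @export
read_ped_map <- function(ped_path, map_path, pheno_path = NULL) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map <- strsplit(trimws(map_lines), "[ \t]+")
  bad <- which(lengths(map) != 4L)
  if (length(bad)) {
    stop_format("MAP line %d: expected 4 fields, found %d", bad[1],
                length(map[[bad[1]]]))
  }
  map <- do.call(rbind, map)
  snp_ids <- map[, 2]
  if (anyDuplicated(snp_ids)) stop_format("MAP: duplicate snp_id")
  p <- length(snp_ids)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  expected <- 6L + 2L * p
  A1 <- matrix("", n, p)
  A2 <- matrix("", n, p)
  subject_ids <- character(n)
  ped_pheno <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != expected) {
      stop_format("PED line %d: expected %d fields, found %d", i, expected,
                  length(f))
    }
    subject_ids[i] <- f[2]
    ped_pheno[i] <- f[6]
    al <- f[-(1:6)]
    ok <- al %in% c("A", "C", "G", "T", "0")
    if (!all(ok)) {
      stop_format("PED line %d: unknown allele character '%s'", i,
                  al[!ok][1])
    }
    A1[i, ] <- al[seq(1, 2 * p, by = 2)]
    A2[i, ] <- al[seq(2, 2 * p, by = 2)]
  }
  if (anyDuplicated(subject_ids)) stop_format("PED: duplicate subject id")

  G <- matrix(NA_integer_, n, p)
  alleles <- matrix(NA_character_, p, 2)
  for (j in seq_len(p)) {
    a1 <- A1[, j]; a2 <- A2[, j]
    miss <- a1 == "0" | a2 == "0"
    obs <- c(a1[!miss], a2[!miss])
    uniq <- sort(unique(obs))
    if (length(uniq) > 2) {
      stop_format("SNP %s: more than two alleles observed (%s)", snp_ids[j],
                  paste(uniq, collapse = ","))
    }
    if (length(uniq) == 0) uniq <- c("A", "A")  # fully missing column
    if (length(uniq) == 1) uniq <- c(uniq, uniq)
    counts <- c(sum(obs == uniq[1]), sum(obs == uniq[2]))
    # minor = less frequent allele; alphabetical tie-break (uniq is sorted)
    minor <- if (counts[2] < counts[1]) uniq[2] else
      if (counts[1] < counts[2]) uniq[1] else uniq[1]
    major <- setdiff(uniq, minor)[1]
    if (is.na(major)) major <- minor
    g <- (a1 == minor) + (a2 == minor)
    g[miss] <- NA_integer_
    G[, j] <- as.integer(g)
    alleles[j, ] <- c(major, minor)
  }

  diagnosis <- ifelse(ped_pheno == "2", "case",
                      ifelse(ped_pheno == "1", "control", NA_character_))
  phenotype <- data.frame(subject_id = subject_ids, diagnosis = diagnosis,
                          apoe_e4_count = NA_integer_,
                          stringsAsFactors = FALSE)
  if (!is.null(pheno_path)) {
    phenotype <- merge_sidecar_phenotype(phenotype, pheno_path)
  }
  ds <- genotype_dataset(subject_ids, snp_ids, chrom = map[, 1],
                         pos = as.integer(map[, 4]), alleles = alleles, G = G,
                         phenotype = phenotype)
  normalize_orientation(ds)
}

merge_sidecar_phenotype <- function(phenotype, pheno_path) {
  side <- read_tsv_file(pheno_path)
  if (!"subject_id" %in% names(side)) {
    stop_format("phenotype sidecar %s lacks a subject_id column", pheno_path)
  }
  idx <- match(phenotype$subject_id, as.character(side$subject_id))
  if ("apoe_e4_count" %in% names(side)) {
    phenotype$apoe_e4_count <- as.integer(side$apoe_e4_count[idx])
  }
  if ("diagnosis" %in% names(side)) {
    d <- as.character(side$diagnosis[idx])
    phenotype$diagnosis <- ifelse(is.na(d), phenotype$diagnosis, d)
  }
  phenotype
}

#' Write a genotype dataset as a PLINK text PED/MAP pair
#'
#' The inverse of [read_ped_map()]: genotype count 0 is written as two major
#' alleles, 1 as major/minor, 2 as two minor alleles, and missing calls as
#' `"0 0"`. Diagnosis goes to PED column 6 (2 = case, 1 = control, 0 =
#' unknown); the APOE e4 count is written to `<ped_path>.pheno.tsv`.
#'
#' @param ds a [genotype_dataset()].
#' @param ped_path,map_path output paths.
#' @return invisibly, the PED path.
#' @export
write_ped_map <- function(ds, ped_path, map_path) {
  map <- data.frame(chrom = ds$chrom, snp_id = ds$snp_ids, cm = 0,
                    pos = ds$pos)
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n <- length(ds$subject_ids)
  p <- length(ds$snp_ids)
  lines <- character(n)
  pheno6 <- ifelse(is.na(ds$phenotype$diagnosis), "0",
                   ifelse(ds$phenotype$diagnosis == "case", "2", "1"))
  for (i in seq_len(n)) {
    g <- ds$G[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, ds$alleles[, 2], ds$alleles[, 1]))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, ds$alleles[, 2], ds$alleles[, 1]))
    calls <- character(2 * p)
    calls[seq(1, 2 * p, 2)] <- a1
    calls[seq(2, 2 * p, 2)] <- a2
    lines[i] <- paste(c(paste0("FAM", i), ds$subject_ids[i], "0", "0", "0",
                        pheno6[i], calls), collapse = " ")
  }
  writeLines(lines, ped_path)
  side <- data.frame(subject_id = ds$subject_ids,
                     diagnosis = ds$phenotype$diagnosis,
                     apoe_e4_count = ds$phenotype$apoe_e4_count)
  write_tsv_file(side, paste0(ped_path, ".pheno.tsv"))
  invisible(ped_path)
}
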