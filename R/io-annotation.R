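# SNP-to-region annotation, GMT gene sets and pathway-group definitions.

#' Read a SNP-to-region annotation table
#'
#' TSV with columns `snp_id` and `region_id`. A region is either a gene symbol
#' or an intergenic label `"GENE_A|GENE_B"` naming the two flanking genes.
#' SNPs of `snp_ids` absent from the table are assigned the region
#' `"UNMAPPED"` (and are excluded from gene- and pathway-level analyses); the
#' number of such SNPs is reported via a message.
#'
#' @param path annotation TSV path.
#' @param snp_ids optional character vector of platform SNPs used to fill in
#'   `"UNMAPPED"` rows.
#' @return a `snp_annotation` data frame with columns `snp_id`, `region_id`,
#'   `region_kind` (`"genic"` or `"intergenic"`).
#' @export
read_annotation <- function(path, snp_ids = NULL) {
  tab <- read_tsv_file(path)
  if (!all(c("snp_id", "region_id") %in% names(tab))) {
    stop_format("%s: annotation needs columns snp_id, region_id", path)
  }
  tab$snp_id <- as.character(tab$snp_id)
  tab$region_id <- as.character(tab$region_id)
  if (any(!nzchar(tab$region_id))) stop_format("%s: empty region_id", path)
  dup <- tab$snp_id[duplicated(tab$snp_id)]
  if (length(dup)) {
    rows <- tab[tab$snp_id %in% dup, ]
    conflicting <- tapply(rows$region_id, rows$snp_id,
                          function(r) length(unique(r)) > 1)
    if (any(conflicting)) {
      stop_format("%s: snp_id %s mapped to conflicting regions", path,
                  names(conflicting)[conflicting][1])
    }
    tab <- tab[!duplicated(tab$snp_id), ]
  }
  snp_annotation(tab$snp_id, tab$region_id, snp_ids = snp_ids)
}

#' Build a SNP annotation object in memory
#'
#' @param snp_id,region_id parallel character vectors.
#' @param snp_ids optional platform SNP list; unannotated SNPs get
#'   `"UNMAPPED"`.
#' @return a `snp_annotation` data frame (see [read_annotation()]).
#' @export
snp_annotation <- function(snp_id, region_id, snp_ids = NULL) {
  ann <- data.frame(snp_id = as.character(snp_id),
                    region_id = as.character(region_id),
                    stringsAsFactors = FALSE)
  if (!is.null(snp_ids)) {
    missing <- setdiff(snp_ids, ann$snp_id)
    if (length(missing)) {
      message(sprintf("%d SNP(s) not in annotation; assigned UNMAPPED",
                      length(missing)))
      ann <- rbind(ann, data.frame(snp_id = missing, region_id = "UNMAPPED"))
    }
    ann <- ann[match(snp_ids, ann$snp_id), , drop = FALSE]
    rownames(ann) <- NULL
  }
  ann$region_kind <- ifelse(grepl("|", ann$region_id, fixed = TRUE),
                            "intergenic", "genic")
  class(ann) <- c("snp_annotation", "data.frame")
  ann
}

#' Genes mapped by a region label
#'
#' A genic region contributes its own symbol; an intergenic `"A|B"` label
#' contributes both flanking genes. `"UNMAPPED"` contributes nothing.
#'
#' @param region_id character vector of region labels.
#' @return list of character vectors, one per label.
#' @export
region_genes <- function(region_id) {
  out <- strsplit(as.character(region_id), "|", fixed = TRUE)
  out[region_id == "UNMAPPED"] <- list(character(0))
  names(out) <- region_id
  out
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated gene-set lines: set id, description, then member
#' gene symbols.
#'
#' @param path GMT path.
#' @return named list mapping set id to a character vector of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop_format("%s line %d: GMT lines need id, description and >= 1 gene",
                path, short[1])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop_format("%s: duplicate set id", path)
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of gene symbol vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(id) {
    desc <- if (is.null(descriptions)) "na" else descriptions[[id]] %||% "na"
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read pathway-group definitions
#'
#' TSV with columns `group_id` and `pathway_id`; group membership order
#' follows file order. Every referenced pathway must exist in `pathways`.
#'
#' @param path groups TSV path.
#' @param pathways named list of gene sets (from [read_gmt()]).
#' @return a `pathway_groups` object: `list(groups = <named list of pathway id
#'   vectors>, pathways = <named list of gene sets>)`.
#' @export
read_groups <- function(path, pathways) {
  tab <- read_tsv_file(path)
  if (!all(c("group_id", "pathway_id") %in% names(tab))) {
    stop_format("%s: groups file needs columns group_id, pathway_id", path)
  }
  pathway_groups(split(as.character(tab$pathway_id),
                       factor(as.character(tab$group_id),
                              levels = unique(as.character(tab$group_id)))),
                 pathways)
}

#' Build a pathway-groups object in memory
#'
#' @param groups named list: group id -> ordered character vector of pathway
#'   ids. A gene may appear in several pathways of the same group (overlap is
#'   expected and is the point of the overlapping group lasso).
#' @param pathways named list: pathway id -> character vector of gene symbols.
#' @return a `pathway_groups` object.
#' @export
pathway_groups <- function(groups, pathways) {
  if (!length(groups) || any(lengths(groups) < 1L)) {
    stop_format("every group needs at least one pathway")
  }
  unknown <- setdiff(unlist(groups), names(pathways))
  if (length(unknown)) {
    stop_format("group references unknown pathway_id %s", unknown[1])
  }
  if (any(lengths(pathways) == 0L)) stop_format("empty gene set in pathways")
  structure(list(groups = groups, pathways = pathways),
            class = "pathway_groups")
}

#' Write pathway-group definitions as TSV
#' @param groups a `pathway_groups` object or a named list of pathway id
#'   vectors.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_groups <- function(groups, path) {
  if (inherits(groups, "pathway_groups")) groups <- groups$groups
  tab <- data.frame(
    group_id = rep(names(groups), lengths(groups)),
    pathway_id = unlist(groups, use.names = FALSE))
  write_tsv_file(tab, path)
  invisible(path)
}

#' Write a SNP annotation table as TSV
#' @param ann a `snp_annotation` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_annotation <- function(ann, path) {
  write_tsv_file(ann[, c("snp_id", "region_id")], path)
  invisible(path)
}
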