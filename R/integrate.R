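# Cross-level signature integration and gene-set over-representation.

#' Construct a signature (the surviving feature set of one analysis)
#'
#' @param level `"SNP"`, `"GENE"` or `"PATHWAY"`.
#' @param task task label (e.g. `"cases_controls"`).
#' @param dataset dataset label.
#' @param items unique character ids surviving the analysis' selection rule.
#' @param item_genes named list mapping each item to its gene symbols (a SNP
#'   item maps to its region's genes -- both flanking genes for an
#'   intergenic region; a pathway item maps to its member genes). Items
#'   absent from the map contribute no genes.
#' @return a `signature_set`.
#' @export
signature_set <- function(level = c("SNP", "GENE", "PATHWAY"), task, dataset,
                          items, item_genes = NULL) {
  level <- match.arg(level)
  items <- unique(as.character(items))
  structure(list(level = level, task = task, dataset = dataset,
                 items = items, item_genes = item_genes %||% list()),
            class = "signature_set")
}

signature_elements <- function(sig, by) {
  if (by == "item") return(sig$items)
  unique(unlist(lapply(sig$items, function(it) {
    g <- sig$item_genes[[it]]
    if (is.null(g)) unlist(region_genes(it)) else g
  })))
}

#' Intersect signatures across levels, tasks or datasets
#'
#' Lists the elements shared by at least two of the supplied signatures,
#' with provenance. With `by = "gene"` SNP and pathway items are first
#' mapped to gene symbols (intergenic labels `"A|B"` contribute both
#' flanking genes), so a gene hit through different SNPs in different
#' analyses still intersects.
#'
#' @param sigs list of at least two [signature_set()] objects.
#' @param by `"gene"` or `"item"`.
#' @return data frame with columns `element`, `n_signatures`, `signatures`
#'   (semicolon-separated `level:task:dataset` labels) and
#'   `supporting_items`.
#' @export
intersect_signatures <- function(sigs, by = c("gene", "item")) {
  by <- match.arg(by)
  if (length(sigs) < 2) stop_format("need at least two signatures")
  labels <- vapply(sigs, function(s) {
    paste(s$level, s$task, s$dataset, sep = ":")
  }, "")
  element_sets <- lapply(sigs, signature_elements, by = by)
  all_elements <- sort(unique(unlist(element_sets)))
  rows <- lapply(all_elements, function(el) {
    hit <- vapply(element_sets, function(set) el %in% set, TRUE)
    if (sum(hit) < 2) return(NULL)
    support <- vapply(which(hit), function(i) {
      items <- if (by == "item") el else {
        sigs[[i]]$items[vapply(sigs[[i]]$items, function(it) {
          g <- sigs[[i]]$item_genes[[it]]
          el %in% (if (is.null(g)) unlist(region_genes(it)) else g)
        }, TRUE)]
      }
      paste(items, collapse = ",")
    }, "")
    data.frame(element = el, n_signatures = sum(hit),
               signatures = paste(labels[hit], collapse = ";"),
               supporting_items = paste(support, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(element = character(0), n_signatures = integer(0),
                      signatures = character(0),
                      supporting_items = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(-out$n_signatures, out$element), , drop = FALSE]
}

#' Gene-set over-representation by the hypergeometric test
#'
#' For each gene set, the upper-tail hypergeometric probability of the
#' observed overlap with the query (`P[X >= k]`, `X ~
#' Hypergeom(N, K, n_q)`) -- identical to one-sided Fisher's exact on the
#' 2x2 table -- with Benjamini-Hochberg adjustment across all tested sets.
#' Sets are intersected with the universe before testing; sets with no
#' overlap report `p = 1`.
#'
#' @param query character vector of query gene symbols (must be contained in
#'   the universe).
#' @param gene_sets named list of gene symbol vectors (e.g. [read_gmt()]).
#' @param universe character vector of all testable genes (e.g. every gene
#'   mappable on the platform).
#' @param alpha significance level for the `significant` flag (on `p_adj`).
#' @return an `enrichment_result` data frame sorted by `p_adj` then `p`:
#'   columns `set_id`, `k`, `n_query`, `set_size`, `universe_size`, `p`,
#'   `p_adj`, `significant`, `genes`.
#' @export
enrich_gene_sets <- function(query, gene_sets, universe, alpha = 0.05) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!length(query) || !length(universe)) {
    stop_format("query and universe must be non-empty")
  }
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop_format("query gene %s is not in the universe", outside[1])
  }
  N <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(gene_sets[[id]], universe)
    K <- length(set)
    hits <- intersect(set, query)
    k <- length(hits)
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n_q, lower.tail = FALSE)
    data.frame(set_id = id, k = k, n_query = n_q, set_size = K,
               universe_size = N, p = clamp_p(p),
               genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_adj, out$p, out$set_id),
             c("set_id", "k", "n_query", "set_size", "universe_size", "p",
               "p_adj", "significant", "genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# ---- evidence extraction for the global signature ---------------------------

#' Evidence rows from a SNP-level scan
#'
#' Genes of the per-chromosome SNP signatures, with strength
#' `1 - selection_frequency` (smaller is stronger, comparable to a
#' p-value's direction).
#'
#' @param scan list of `resampling_result` from [snp_scan()].
#' @param annotation a `snp_annotation`.
#' @param task,dataset provenance labels.
#' @return an evidence data frame (`gene`, `level`, `task`, `dataset`,
#'   `item`, `strength`).
#' @export
evidence_from_snp_scan <- function(scan, annotation, task, dataset) {
  rows <- list()
  for (r in scan) {
    for (snp in r$signature) {
      region <- annotation$region_id[match(snp, annotation$snp_id)]
      for (gene in unlist(region_genes(region))) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, level = "SNP", task = task, dataset = dataset,
          item = snp, strength = 1 - unname(r$selection_frequency[snp]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_evidence())
  do.call(rbind, rows)
}

#' Evidence rows from a gene scan
#'
#' Genes of regions significant under any of the three tests, with strength
#' the SKAT p-value.
#'
#' @param gs a `gene_scan` from [run_gene_scan()].
#' @param task,dataset provenance labels.
#' @return an evidence data frame.
#' @export
evidence_from_gene_scan <- function(gs, task, dataset) {
  sig <- gs[gs$sig_burden | gs$sig_skat | gs$sig_skato, , drop = FALSE]
  if (!nrow(sig)) return(empty_evidence())
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    genes <- unlist(region_genes(sig$region_id[i]))
    if (!length(genes)) return(NULL)
    data.frame(gene = genes, level = "GENE", task = task, dataset = dataset,
               item = sig$region_id[i], strength = sig$p_skat[i],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty_evidence())
  do.call(rbind, rows)
}

#' Evidence rows from a pathway scan
#'
#' Member genes of the selected pathways, with strength `1 - test_score` of
#' the group.
#'
#' @param scan named list of `pathway_selection` from [pathway_scan()].
#' @param groups the `pathway_groups` analysed.
#' @param task,dataset provenance labels.
#' @return an evidence data frame.
#' @export
evidence_from_pathway_scan <- function(scan, groups, task, dataset) {
  rows <- list()
  for (s in scan) {
    for (pw in s$selected_pathways) {
      for (gene in groups$pathways[[pw]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, level = "PATHWAY", task = task, dataset = dataset,
          item = pw, strength = 1 - s$test_score, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_evidence())
  do.call(rbind, rows)
}

empty_evidence <- function() {
  data.frame(gene = character(0), level = character(0), task = character(0),
             dataset = character(0), item = character(0),
             strength = numeric(0))
}

#' Build the global cross-level signature report
#'
#' Aggregates evidence rows from all completed analyses into one ranked
#' gene table: per gene, the number of distinct supporting analyses (a
#' level x task x dataset combination counts once), the levels, tasks and
#' datasets supporting it, and the best (smallest) per-analysis strength.
#' Genes are ranked by support count (descending), then best strength
#' (ascending), then gene id.
#'
#' @param evidence list of evidence data frames (from the
#'   `evidence_from_*` helpers) or a single combined data frame.
#' @return a `global_signature` data frame: `gene`, `n_analyses`, `levels`,
#'   `tasks`, `datasets`, `best_strength`, `items`.
#' @export
build_global_signature <- function(evidence) {
  if (is.data.frame(evidence)) evidence <- list(evidence)
  ev <- do.call(rbind, evidence)
  if (is.null(ev) || !nrow(ev)) {
    out <- data.frame(gene = character(0), n_analyses = integer(0),
                      levels = character(0), tasks = character(0),
                      datasets = character(0), best_strength = numeric(0),
                      items = character(0))
    class(out) <- c("global_signature", "data.frame")
    return(out)
  }
  ev$analysis <- paste(ev$level, ev$task, ev$dataset, sep = ":")
  genes <- sort(unique(ev$gene))
  rows <- lapply(genes, function(g) {
    sub <- ev[ev$gene == g, , drop = FALSE]
    data.frame(gene = g,
               n_analyses = length(unique(sub$analysis)),
               levels = paste(sort(unique(sub$level)), collapse = ";"),
               tasks = paste(sort(unique(sub$task)), collapse = ";"),
               datasets = paste(sort(unique(sub$dataset)), collapse = ";"),
               best_strength = min(sub$strength),
               items = paste(sort(unique(sub$item)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_analyses, out$best_strength, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("global_signature", "data.frame")
  out
}
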