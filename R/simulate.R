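# Seeded synthetic GWAS generator: genotypes with LD blocks and a realistic
# MAF spectrum, a logistic disease model with planted small-effect causal
# SNPs and an optional APOE-like high-effect locus, plus annotation and
# pathway-group files, so every downstream stage is testable offline.

#' Configuration of the synthetic GWAS generator
#'
#' Defaults describe a small case/control cohort of the kind the analysis
#' stages expect: a few hundred subjects, LD blocks of ~10 SNPs with moderate
#' within-block haplotype correlation, a common-variant MAF spectrum and a low
#' missing-call rate. All randomness descends from `seed` (mandatory).
#'
#' @param n_subjects number of subjects.
#' @param n_snps number of biallelic SNPs.
#' @param n_chromosomes chromosomes; LD blocks are assigned round-robin.
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho within-block AR(1) haplotype correlation, in `[0, 1)`.
#' @param maf_range `(low, high)` bounds of the uniform MAF spectrum, within
#'   `(0, 0.5]`.
#' @param causal_snps optional data frame with columns `snp_index`, `beta`:
#'   planted causal SNPs with per-allele log-odds effects.
#' @param apoe_like optional `list(snp_index, beta, also_drives_e4_label)`
#'   describing a single high-effect locus; when `also_drives_e4_label` is
#'   `TRUE` the APOE e4 allele count equals the genotype at that SNP (the
#'   locus is then never masked as missing).
#' @param missing_rate completely-at-random missing-call rate, in `[0, 0.2]`.
#' @param prevalence_intercept baseline log-odds of being a case; `NA`
#'   centres the linear predictor at its expected value, giving an expected
#'   case fraction of one half regardless of the planted effects.
#' @param seed integer RNG seed (no implicit entropy).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 400, n_snps = 500,
                              n_chromosomes = 5, ld_block_size = 10,
                              ld_rho = 0.4, maf_range = c(0.05, 0.5),
                              causal_snps = NULL, apoe_like = NULL,
                              missing_rate = 0.02, prevalence_intercept = 0,
                              seed) {
  if (missing(seed) || is.null(seed)) stop_format("seed is mandatory")
  if (ld_rho < 0 || ld_rho >= 1) stop_format("ld_rho must be in [0, 1)")
  if (missing_rate < 0 || missing_rate > 0.2) {
    stop_format("missing_rate must be in [0, 0.2]")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop_format("maf_range must satisfy 0 < low <= high <= 0.5")
  }
  if (!is.null(causal_snps)) {
    idx <- causal_snps$snp_index
    if (anyDuplicated(idx) || any(idx < 1 | idx > n_snps)) {
      stop_format("causal snp_index values must be distinct and in 1..n_snps")
    }
  }
  if (!is.null(apoe_like)) {
    if (apoe_like$snp_index < 1 || apoe_like$snp_index > n_snps) {
      stop_format("apoe_like snp_index out of range")
    }
    apoe_like$also_drives_e4_label <-
      isTRUE(apoe_like$also_drives_e4_label)
  }
  structure(list(n_subjects = n_subjects, n_snps = n_snps,
                 n_chromosomes = n_chromosomes,
                 ld_block_size = ld_block_size, ld_rho = ld_rho,
                 maf_range = maf_range, causal_snps = causal_snps,
                 apoe_like = apoe_like, missing_rate = missing_rate,
                 prevalence_intercept = prevalence_intercept,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate genotypes with block-wise LD
#'
#' A Gaussian-threshold (copula) haplotype model: per LD block, each haplotype
#' is a latent AR(1) Gaussian vector thresholded at the allele-frequency
#' quantile, and the genotype is the sum of two independent haplotypes, so
#' each SNP is marginally Hardy-Weinberg at its drawn MAF while neighbouring
#' SNPs within a block are correlated. Missing calls are masked completely at
#' random. Phenotype fields are left `NA`; fill them with
#' [simulate_phenotypes()].
#'
#' @param cfg a [simulation_config()].
#' @return a [genotype_dataset()] (genotypes only).
#' @export
simulate_genotypes <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_subjects
    p <- cfg$n_snps
    maf <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
    block_id <- ceiling(seq_len(p) / cfg$ld_block_size)
    chrom <- as.character(((block_id - 1L) %% cfg$n_chromosomes) + 1L)
    G <- matrix(0L, n, p)
    for (b in unique(block_id)) {
      js <- which(block_id == b)
      thr <- stats::qnorm(maf[js])
      for (h in 1:2) {
        z <- matrix(0, n, length(js))
        z[, 1] <- stats::rnorm(n)
        if (length(js) > 1) {
          for (k in 2:length(js)) {
            z[, k] <- cfg$ld_rho * z[, k - 1] +
              sqrt(1 - cfg$ld_rho^2) * stats::rnorm(n)
          }
        }
        hap <- sweep(z, 2, thr, "<") * 1L
        G[, js] <- G[, js] + hap
      }
    }
    if (cfg$missing_rate > 0) {
      mask <- matrix(stats::runif(n * p) < cfg$missing_rate, n, p)
      if (!is.null(cfg$apoe_like) && cfg$apoe_like$also_drives_e4_label) {
        mask[, cfg$apoe_like$snp_index] <- FALSE
      }
      G[mask] <- NA_integer_
    }
    # 1-based positions increasing within each chromosome
    pos <- integer(p)
    for (ch in unique(chrom)) {
      js <- which(chrom == ch)
      pos[js] <- 10000L * seq_along(js)
    }
    phenotype <- data.frame(
      subject_id = sprintf("subj%04d", seq_len(n)),
      diagnosis = NA_character_, apoe_e4_count = NA_integer_,
      stringsAsFactors = FALSE)
    genotype_dataset(
      subject_ids = phenotype$subject_id,
      snp_ids = sprintf("snp%05d", seq_len(p)),
      chrom = chrom, pos = pos,
      alleles = cbind(rep("A", p), rep("C", p)),
      G = G, phenotype = phenotype)
  })
}

#' Simulate case/control and APOE phenotypes on top of genotypes
#'
#' The disease model is logistic: each subject's case probability is
#' `plogis(prevalence_intercept + sum_j beta_j g_ij)` over the planted causal
#' SNPs (plus the APOE-like locus effect when configured), with missing
#' genotypes imputed to their expected dosage `2 * MAF` in the linear
#' predictor. The APOE e4 count either equals the genotype at the APOE-like
#' locus (`also_drives_e4_label`) or is drawn independently with carrier
#' frequencies 0.6/0.3/0.1 for 0/1/2 alleles.
#'
#' @param geno a [genotype_dataset()] from [simulate_genotypes()].
#' @param cfg the same [simulation_config()].
#' @return `geno` with its phenotype table filled in.
#' @export
simulate_phenotypes <- function(geno, cfg) {
  with_seed(cfg$seed + 1L, {
    n <- length(geno$subject_ids)
    maf <- snp_maf(geno)
    effects <- cfg$causal_snps
    if (!is.null(cfg$apoe_like)) {
      effects <- rbind(effects,
                       data.frame(snp_index = cfg$apoe_like$snp_index,
                                  beta = cfg$apoe_like$beta))
    }
    intercept <- cfg$prevalence_intercept
    if (is.na(intercept)) {
      # centre the linear predictor: expected case fraction ~ 1/2
      intercept <- if (is.null(effects)) 0 else
        -sum(effects$beta * 2 * maf[effects$snp_index])
    }
    lp <- rep(intercept, n)
    if (!is.null(effects)) {
      for (r in seq_len(nrow(effects))) {
        j <- effects$snp_index[r]
        g <- geno$G[, j]
        g[is.na(g)] <- 2 * maf[j]
        lp <- lp + effects$beta[r] * g
      }
    }
    diagnosis <- ifelse(stats::rbinom(n, 1, stats::plogis(lp)) == 1,
                        "case", "control")
    if (!is.null(cfg$apoe_like) && cfg$apoe_like$also_drives_e4_label) {
      e4 <- geno$G[, cfg$apoe_like$snp_index]
      stopifnot(!anyNA(e4))
    } else {
      e4 <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    }
    geno$phenotype$diagnosis <- diagnosis
    geno$phenotype$apoe_e4_count <- as.integer(e4)
    geno
  })
}

#' Simulate SNP annotation, pathways and pathway groups
#'
#' Consecutive SNPs within a chromosome are grouped into pseudo-genes of
#' `gene_size` SNPs; pseudo-genes are assembled sequentially into pathways of
#' `genes_per_pathway` genes, and pathways into groups of
#' `pathways_per_group`. Within a group, a fraction `overlap_fraction` of each
#' pathway's genes is shared with the next pathway, so a gene can belong to
#' two pathways of the same group (the structure the overlapping group lasso
#' exploits). All genes containing planted causal SNPs are concentrated into
#' one designated causal pathway (the first pathway of the first group) and
#' removed from every other pathway, so ground-truth recovery is checkable by
#' set inclusion.
#'
#' @param geno a [genotype_dataset()].
#' @param cfg the [simulation_config()] used to generate it.
#' @param gene_size SNPs per pseudo-gene.
#' @param genes_per_pathway core genes per pathway.
#' @param pathways_per_group pathways per group.
#' @param overlap_fraction fraction of a pathway's core genes shared with the
#'   next pathway of the same group, in `[0, 1)`.
#' @return list with elements `annotation` (a `snp_annotation`), `groups` (a
#'   `pathway_groups`), `causal_pathway` (pathway id or `NA`), `causal_genes`,
#'   and `gene_snps` (named list gene -> SNP ids).
#' @export
simulate_annotation <- function(geno, cfg, gene_size = 5,
                                genes_per_pathway = 4, pathways_per_group = 4,
                                overlap_fraction = 0.25) {
  p <- length(geno$snp_ids)
  gene_of <- character(p)
  gene_snps <- list()
  for (ch in unique(geno$chrom)) {
    js <- which(geno$chrom == ch)
    k <- ceiling(seq_along(js) / gene_size)
    for (g in unique(k)) {
      gene <- sprintf("GEN%s_%02d", ch, g)
      gene_of[js[k == g]] <- gene
      gene_snps[[gene]] <- geno$snp_ids[js[k == g]]
    }
  }
  annotation <- snp_annotation(geno$snp_ids, gene_of)

  genes <- names(gene_snps)
  causal_genes <- character(0)
  if (!is.null(cfg$causal_snps)) {
    causal_genes <- unique(gene_of[cfg$causal_snps$snp_index])
  }
  n_pw <- max(1L, ceiling(length(genes) / genes_per_pathway))
  pw_ids <- sprintf("PW%02d", seq_len(n_pw))
  core <- split(genes, rep(seq_len(n_pw), each = genes_per_pathway,
                           length.out = length(genes)))
  group_of <- ceiling(seq_len(n_pw) / pathways_per_group)
  n_ov <- round(overlap_fraction * genes_per_pathway)
  pathways <- vector("list", n_pw)
  names(pathways) <- pw_ids
  for (i in seq_len(n_pw)) {
    members <- core[[i]]
    if (n_ov > 0 && i < n_pw && group_of[i + 1] == group_of[i]) {
      members <- union(members, utils::head(core[[i + 1]], n_ov))
    }
    pathways[[i]] <- members
  }
  causal_pathway <- NA_character_
  if (length(causal_genes)) {
    causal_pathway <- pw_ids[1]
    pathways <- lapply(pathways, setdiff, y = causal_genes)
    pathways[[causal_pathway]] <- union(causal_genes,
                                        pathways[[causal_pathway]])
    drop <- lengths(pathways) == 0L
    pathways <- pathways[!drop]
    group_of <- group_of[!drop]
  }
  groups <- split(names(pathways),
                  sprintf("GRP%02d", group_of))
  list(annotation = annotation,
       groups = pathway_groups(groups, pathways),
       causal_pathway = causal_pathway,
       causal_genes = causal_genes,
       gene_snps = gene_snps)
}

#' Generate a complete synthetic GWAS study
#'
#' Runs [simulate_genotypes()], [simulate_phenotypes()] and
#' [simulate_annotation()] under the config's seed and, when `dir` is given,
#' writes the dosage TSV triplet, the annotation TSV, the GMT gene sets, the
#' groups TSV and a JSON manifest of the planted ground truth (causal SNP
#' ids and effects, APOE-like locus, causal pathway, seed).
#'
#' @param cfg a [simulation_config()].
#' @param dir optional output directory (created if absent).
#' @param ... passed to [simulate_annotation()].
#' @return list with `dataset`, `annotation`, `groups`, `manifest` (and
#'   `causal_pathway`, `gene_snps`).
#' @export
simulate_gwas <- function(cfg, dir = NULL, ...) {
  ds <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  ann <- simulate_annotation(ds, cfg, ...)
  manifest <- list(
    seed = cfg$seed,
    n_subjects = cfg$n_subjects,
    n_snps = cfg$n_snps,
    causal_snp_ids = if (is.null(cfg$causal_snps)) character(0) else
      ds$snp_ids[cfg$causal_snps$snp_index],
    causal_betas = if (is.null(cfg$causal_snps)) numeric(0) else
      cfg$causal_snps$beta,
    apoe_like_snp = if (is.null(cfg$apoe_like)) NA_character_ else
      ds$snp_ids[cfg$apoe_like$snp_index],
    causal_pathway = ann$causal_pathway,
    causal_genes = ann$causal_genes)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_dosage_tsv(ds, file.path(dir, "genotypes.tsv"))
    write_annotation(ann$annotation, file.path(dir, "annotation.tsv"))
    write_gmt(ann$groups$pathways, file.path(dir, "pathways.gmt"))
    write_groups(ann$groups, file.path(dir, "groups.tsv"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(dataset = ds, annotation = ann$annotation, groups = ann$groups,
       causal_pathway = ann$causal_pathway, gene_snps = ann$gene_snps,
       manifest = manifest)
}
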