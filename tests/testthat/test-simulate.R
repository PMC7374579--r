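# Synthetic GWAS generator: determinism, marginal genotype law, LD
# structure, phenotype model and annotation construction.

test_that("generation is fully deterministic under a fixed seed", {
  cfg <- simulation_config(n_subjects = 40, n_snps = 20, n_chromosomes = 2,
                           causal_snps = data.frame(snp_index = 1, beta = 1),
                           seed = 99)
  a <- simulate_gwas(cfg)
  b <- simulate_gwas(cfg)
  expect_identical(a$dataset, b$dataset)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$manifest, b$manifest)
})

test_that("MAF spectrum matches the configured range", {
  cfg <- simulation_config(n_subjects = 2000, n_snps = 40, n_chromosomes = 2,
                           ld_rho = 0, maf_range = c(0.3, 0.3),
                           missing_rate = 0, seed = 21)
  ds <- simulate_genotypes(cfg)
  expect_true(all(abs(snp_maf(ds) - 0.3) < 0.05))
})

test_that("ld_rho = 0 gives uncorrelated adjacent SNPs; ld_rho > 0 does not", {
  cfg0 <- simulation_config(n_subjects = 2000, n_snps = 20,
                            n_chromosomes = 1, ld_block_size = 10,
                            ld_rho = 0, missing_rate = 0, seed = 22)
  ds0 <- simulate_genotypes(cfg0)
  r0 <- sapply(1:9, function(j) cor(ds0$G[, j], ds0$G[, j + 1]))
  expect_true(all(abs(r0) < 0.1))

  cfg7 <- simulation_config(n_subjects = 2000, n_snps = 20,
                            n_chromosomes = 1, ld_block_size = 10,
                            ld_rho = 0.7, missing_rate = 0, seed = 22)
  ds7 <- simulate_genotypes(cfg7)
  r7 <- sapply(1:9, function(j) cor(ds7$G[, j], ds7$G[, j + 1]))
  expect_true(mean(r7) > 0.3)
})

test_that("independent SNPs are Hardy-Weinberg at their drawn MAF", {
  cfg <- simulation_config(n_subjects = 5000, n_snps = 12, n_chromosomes = 1,
                           ld_rho = 0, maf_range = c(0.1, 0.4),
                           missing_rate = 0, seed = 23)
  ds <- simulate_genotypes(cfg)
  maf <- snp_maf(ds)
  for (j in seq_len(12)) {
    p <- maf[j]
    expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    observed <- tabulate(ds$G[, j] + 1L, 3L)
    gof <- suppressWarnings(chisq.test(observed, p = expected))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("null phenotype model yields a balanced cohort", {
  cfg <- simulation_config(n_subjects = 1000, n_snps = 10, n_chromosomes = 1,
                           prevalence_intercept = 0, seed = 24)
  sim <- simulate_gwas(cfg)
  frac <- mean(sim$dataset$phenotype$diagnosis == "case")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("a planted log(2) effect reproduces its odds ratio", {
  cfg <- simulation_config(
    n_subjects = 5000, n_snps = 10, n_chromosomes = 1, ld_rho = 0,
    maf_range = c(0.3, 0.3), missing_rate = 0,
    causal_snps = data.frame(snp_index = 1, beta = log(2)),
    prevalence_intercept = NA, seed = 25)
  sim <- simulate_gwas(cfg)
  g <- sim$dataset$G[, 1]
  case <- sim$dataset$phenotype$diagnosis == "case"
  odds <- function(sel) sum(case[sel]) / sum(!case[sel])
  or_10 <- odds(g == 1) / odds(g == 0)
  expect_lt(abs(or_10 - 2), 0.5)
})

test_that("the APOE-like locus can drive the e4 label deterministically", {
  sim <- make_small_signal_sim(seed = 26)
  apoe_snp <- sim$manifest$apoe_like_snp
  j <- match(apoe_snp, sim$dataset$snp_ids)
  labs <- make_task_labels(sim$dataset, "apoe_e4")
  g <- sim$dataset$G[match(labs$subject_ids, sim$dataset$subject_ids), j]
  pred <- ifelse(g >= 1, 1, -1)
  expect_equal(balanced_accuracy(labs$y, pred), 1.0)
})

test_that("annotation maps every SNP and concentrates causal genes", {
  sim <- make_small_signal_sim(seed = 27)
  expect_false(any(sim$annotation$region_id == "UNMAPPED"))
  # every causal gene is inside the designated causal pathway
  pw <- sim$groups$pathways[[sim$causal_pathway]]
  expect_true(all(sim$manifest$causal_genes %in% pw))
  # and removed from every other pathway
  others <- sim$groups$pathways[names(sim$groups$pathways) !=
                                  sim$causal_pathway]
  expect_false(any(unlist(others) %in% sim$manifest$causal_genes))
})

test_that("zero overlap fraction gives disjoint pathways within a group", {
  cfg <- simulation_config(n_subjects = 30, n_snps = 40, n_chromosomes = 2,
                           seed = 28)
  ds <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  ann <- simulate_annotation(ds, cfg, gene_size = 2, genes_per_pathway = 2,
                             pathways_per_group = 2, overlap_fraction = 0)
  for (gid in names(ann$groups$groups)) {
    sets <- ann$groups$pathways[ann$groups$groups[[gid]]]
    if (length(sets) < 2) next
    expect_length(intersect(sets[[1]], sets[[2]]), 0)
  }
  ann2 <- simulate_annotation(ds, cfg, gene_size = 2, genes_per_pathway = 2,
                              pathways_per_group = 2, overlap_fraction = 0.5)
  overlaps <- vapply(names(ann2$groups$groups), function(gid) {
    sets <- ann2$groups$pathways[ann2$groups$groups[[gid]]]
    if (length(sets) < 2) return(0L)
    length(intersect(sets[[1]], sets[[2]]))
  }, 0L)
  expect_true(any(overlaps > 0))
})

test_that("written fixtures are readable and pass dataset invariants", {
  dir <- withr::local_tempdir()
  simulate_gwas(simulation_config(
    n_subjects = 25, n_snps = 12, n_chromosomes = 3, ld_block_size = 5,
    ld_rho = 0.3, maf_range = c(0.1, 0.5),
    causal_snps = data.frame(snp_index = 1:2, beta = log(2.5)),
    missing_rate = 0.02, prevalence_intercept = NA, seed = 29), dir = dir)
  ds <- read_dosage_tsv(file.path(dir, "genotypes.tsv"))
  expect_s3_class(ds, "genotype_dataset")
  expect_silent(validate_genotype_dataset(ds))
  ann <- read_annotation(file.path(dir, "annotation.tsv"),
                         snp_ids = ds$snp_ids)
  expect_false(any(ann$region_id == "UNMAPPED"))
  sets <- read_gmt(file.path(dir, "pathways.gmt"))
  groups <- read_groups(file.path(dir, "groups.tsv"), sets)
  expect_s3_class(groups, "pathway_groups")
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 29)
})
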