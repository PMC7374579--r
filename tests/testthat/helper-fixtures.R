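# Small in-code fixtures shared across test files.

# A tiny hand-built dataset: 4 subjects x 3 SNPs with one missing call.
make_toy_dataset <- function() {
  G <- matrix(c(0L, 1L, 2L, 1L,
                0L, 0L, 1L, NA,
                1L, 1L, 1L, 1L), nrow = 4)
  genotype_dataset(
    subject_ids = paste0("s", 1:4),
    snp_ids = c("rs1", "rs2", "rs3"),
    chrom = c("1", "1", "2"),
    pos = c(100L, 200L, 100L),
    alleles = cbind(c("A", "A", "C"), c("G", "C", "T")),
    G = G,
    phenotype = data.frame(
      subject_id = paste0("s", 1:4),
      diagnosis = c("case", "control", "case", "control"),
      apoe_e4_count = c(0L, 1L, 2L, 0L),
      stringsAsFactors = FALSE))
}

# Simulated study with planted signal, small enough for fast tests.
make_small_signal_sim <- function(seed = 5, n = 200, p = 60) {
  cfg <- simulation_config(
    n_subjects = n, n_snps = p, n_chromosomes = 3, ld_block_size = 5,
    ld_rho = 0.3, maf_range = c(0.1, 0.5),
    causal_snps = data.frame(snp_index = 1:5, beta = log(2.5)),
    apoe_like = list(snp_index = min(30, p), beta = log(4),
                     also_drives_e4_label = TRUE),
    missing_rate = 0.02, prevalence_intercept = NA, seed = seed)
  simulate_gwas(cfg)
}
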