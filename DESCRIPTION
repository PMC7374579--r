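Package: telegwas
Type: Package
Title: Multi-Level GWAS Analysis with Sparse Multivariate Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-resolution ("telescope") analysis of case/control genotype
    data. The same cohort is analysed at three biological levels: per-chromosome
    sparse l1l2 (elastic-net) classification inside a resampling framework with
    matched permutation batches (SNP level), region-based association tests --
    weighted burden, SKAT and SKAT-O (gene level), and overlapping group-lasso
    selection of pathways within curated pathway groups (pathway level) --
    followed by cross-level signature integration and gene-set
    over-representation. Includes readers and writers for PLINK text PED/MAP, a
    dosage TSV dialect, SNP-to-region annotation, GMT gene sets and pathway
    groups, plus a fully seeded synthetic GWAS generator (MAF spectrum, LD
    blocks, planted causal SNPs, an APOE-like high-effect locus) so the whole
    pipeline is testable without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
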