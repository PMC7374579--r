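---
title: "Multi-level GWAS analysis with telegwas: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level GWAS analysis with telegwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telegwas)
```

## The problem and the approach

Late-onset complex diseases are rarely explained by single large-effect
variants: the working hypothesis behind multivariate GWAS analysis is that
many variants of individually small effect act together, possibly through
shared pathways. Univariate per-SNP testing is poorly suited to that
structure. `telegwas` implements a three-resolution ("telescope") strategy
on one case/control cohort:

1. **SNP level** — each chromosome is analysed separately with a sparse
   l1l2 (elastic-net) classifier inside a Monte-Carlo resampling framework;
   a matched *permutation batch* (identical experiments on shuffled labels)
   provides the chance reference, and the distance between the two
   balanced-accuracy distributions measures how reliable a chromosome's
   signal is.
2. **Gene level** — SNPs are grouped by gene or intergenic region and each
   region is tested with three region-based association tests: a weighted
   burden test, the variance-component score test (SKAT) and their optimal
   combination (SKAT-O), against a conservative genome-wide threshold.
3. **Pathway level** — SNPs are mapped through genes into curated pathway
   *groups*; within a group the overlapping group lasso selects a sparse
   set of pathways while letting a gene count for every pathway that
   contains it.

Signatures from (up to) two binary tasks — case/control diagnosis and
APOE-e4 carrier status — and the three levels are intersected at the gene
level and ranked into a *global signature*; gene lists can additionally be
characterised by hypergeometric over-representation against gene sets.

Two classification tasks are supported because they ask different
questions: `cases_controls` asks what distinguishes diagnosed cases from
healthy controls; `apoe_e4` asks what co-segregates with the major known
risk allele, which can expose a cumulative polygenic profile around the
APOE locus even in cohorts where the locus itself is not on the platform.

## Genotype representation

Raw genotypes are minor-allele counts in {0, 1, 2}. The minor-allele
orientation is recomputed from the data on every load (ties at frequency
0.5 broken alphabetically), so MAF is always in [0, 0.5] regardless of
input metadata. Missing calls are imputed to the mean dosage `2p` — the
neutral value under standardisation — and never imputed against a
reference panel (the pipeline is designed for unimputed platform data).

`encode_genotypes()` makes the categorical counts continuous before the
sparse classifiers. Three schemes are shipped, and every results file
records which one was used:

* `standardized` (default): `x = (g - 2p) / sqrt(2p(1-p))`. Centred at the
  empirical mean dosage (2p *is* the empirical mean, so columns are
  exactly mean-zero) and scaled by the Hardy-Weinberg standard deviation.
  This is the field-standard dosage standardisation; empirical column
  variances are ~1 to the extent the cohort is in Hardy-Weinberg
  proportions.
* `weighted`: `x = g * dbeta(p, 1, 25)`, the SKAT-convention rare-variant
  up-weighting, inducing an explicit frequency-based prioritisation.
* `raw`: the counts themselves (identity apart from imputation).

The gene-level tests always operate on raw counts, not on the encoding,
because the score-test framework is defined on genotypes.

## SNP level: l1l2 classification with permutation batches

The classifier solves label regression with elastic-net penalties,

$$\min_{w, b}\ \tfrac1n\lVert y - Xw - b\mathbf 1\rVert_2^2
  + \mu\lVert w\rVert_2^2 + \tau\lVert w\rVert_1,
  \qquad \hat y = \operatorname{sign}(Xw + b),$$

by monotone FISTA: accelerated proximal gradient with step $1/L$,
$L = 2(\sigma_{\max}^2(X)/n + \mu)$, where the extrapolated step is kept
only when it lowers the objective (otherwise a plain proximal step is
taken and the momentum restarts). The objective is therefore
non-increasing by construction, the null-solution threshold
$\tau_{\max} = \max_j |(2/n)x_j^\top(y - \bar y)|$ is exact, and on
orthonormal designs the solution matches the closed form
$\mathrm{soft}((1/n)x_j^\top y, \tau/2)/(1+\mu)$.

Each resampling experiment draws a stratified 75/25 learning/test split,
selects $\tau$ on the learning set by 3-fold stratified cross-validation
maximising balanced accuracy (ties towards the largest $\tau$, i.e. the
sparsest model), refits, and records test balanced accuracy, MCC and the
selected SNP set. Defaults: $\mu = 10^{-2}$; a 20-point log-spaced
$\tau$-grid in $[10^{-3}\tau_{\max}, \tau_{\max}]$ derived per learning
set; 100 regular and 100 permutation experiments; signature =
selection frequency $\ge 0.75$ over the regular batch.

### Reliability: what the permutation batch can and cannot calibrate

A chromosome is *reliable* when the regular batch outperforms the
permutation batch beyond chance. Operationalising "distance between the
two distributions" needs care, because the two batches have different
dependence structures:

* all regular experiments share one label vector and one cohort, so their
  accuracies are positively correlated across splits, and — crucially — a
  *realised* spurious genotype-phenotype alignment (the best of many
  sample correlations, a max-type and therefore heavy-tailed quantity)
  shifts the whole regular batch coherently;
* each permutation experiment reshuffles the labels, so permutation
  accuracies are nearly independent draws that mix split noise with
  *fresh* alignment draws.

A rank-sum test between the two batches treats all values as exchangeable
and proved strongly anticonservative on null data in calibration runs. We
therefore report the rank-sum p-value only as a descriptive diagnostic
(`p_wilcoxon`) and base the `reliable` flag on a variance-decomposed
one-sided z-statistic for the difference of batch means with

$$\widehat{\mathrm{se}}^2 = \max(v_P - v_R, 0)
  + v_R\left(\rho_0 + \tfrac{1-\rho_0}{n_R}\right) + \tfrac{v_P}{n_P},$$

where $v_R, v_P$ are the within-batch variances and $\rho_0 = 0.3$ is a
conservative bound on the within-regular-batch correlation, fixed from a
development-time calibration study. The first term absorbs the
alignment variance visible in the permutation batch; the second term
refuses to average the regular batch's correlated split noise all the way
down.

Two limitations are documented rather than hidden. First, the decomposition
between dataset-level alignment and within-batch correlation is not
identifiable from a single dataset (for exchangeable correlation the two
trade off exactly), which is why $\rho_0$ is a fixed design constant and
not an estimate. Second, a sufficiently extreme realised spurious
alignment is indistinguishable *within one dataset* from true signal of
the same magnitude — no within-dataset statistic separates them; only
independent replication can. The calibrated flag therefore errs on the
conservative side: weak true signals whose separation is comparable to
the null alignment tail will not be flagged. The selection-frequency
signature does not suffer from this trade-off and is reported regardless
of the flag.

## Gene level: burden, SKAT, SKAT-O

With no covariates, the null model is intercept-only logistic:
$\hat\mu_0$ is the case fraction, residuals $r = y - \hat\mu_0$, variance
weight $v = \hat\mu_0(1-\hat\mu_0)$. For a region matrix $G$ with weights
$W = \mathrm{diag}(w_j)$, default $w_j = \mathrm{Beta}(1,25)$ density at
$\mathrm{MAF}_j$:

* **SKAT**: $Q = r^\top G W^2 G^\top r$, null distribution
  $\sum_k \lambda_k \chi^2_1$ with $\lambda_k$ the eigenvalues of
  $W G^\top P_0 G W$, $P_0 = \mathrm{diag}(v) - vv^\top/\sum v$. The tail
  probability is computed by numerical inversion of the characteristic
  function (Imhof's integral, the quantity Davies' algorithm evaluates),
  falling back to the Liu-Lee moment-matching approximation when the
  integral fails (the route used is recorded); a single-eigenvalue mixture
  is evaluated exactly as a scaled chi-square.
* **Burden**: the 1-df score test of the collapsed score
  $s_i = \sum_j w_j g_{ij}$: $Q_B = (s^\top r)^2 / s^\top P_0 s \sim
  \chi^2_1$; a single-SNP region reduces to the single-SNP score test
  exactly.
* **SKAT-O**: $Q_\rho = (1-\rho)Q_{\mathrm{SKAT}} + \rho Q_B$ over a grid
  $\rho \in \{0, 0.01, 0.04, 0.09, 0.25, 0.5, 1\}$. The default
  combination refers the minimum per-$\rho$ p-value to its exact
  asymptotic null by the one-dimensional integration over the shared 1-df
  component carried by the column-mean direction of the score design (the
  SKAT-O construction). A simpler Bonferroni combination
  $\min(1, |{\rm grid}| \cdot \min_\rho p_\rho)$ is available via
  `method = "minp-bonferroni"`, but because the per-$\rho$ p-values are
  strongly correlated it is severely conservative (rejecting at a small
  fraction of its nominal level in calibration runs), so the integration
  route is the default; the test suite verifies the default's type-I
  error on 2000 simulated null regions. Both endpoints are exact: a
  singleton grid at $\rho=0$ or $\rho=1$ reproduces SKAT or burden
  identically.

Genome-wide significance uses the conservative Bonferroni rule
$0.05/\#\mathrm{regions}$ (or a user-supplied fixed threshold). For
example, 36,496 tested regions give $1.37\times10^{-6}$. Each significant
region also reports its top SNP by single-SNP score test, and intergenic
regions keep their `"A|B"` labels so both flanking genes flow into the
integration.

## Pathway level: overlapping group lasso

Within one pathway group, each (SNP, pathway) membership pair becomes one
expanded design column (the latent-duplication formulation); block $g$
collects pathway $g$'s copies, with penalty weight $\sqrt{d_g}$. The fit
minimises logistic loss plus $\lambda \sum_g \sqrt{d_g}\lVert v_g\rVert_2$
by proximal gradient with block soft-thresholding, step
$1/L$, $L = \sigma^2_{\max}([X\ \mathbf 1])/(4n)$ (the logistic curvature
bound), so descent is monotone; $\lambda_{\max}$ (the smallest
all-zero-blocks $\lambda$) is computed at the null intercept. A SNP whose
gene sits in two pathways can survive through either copy; its effective
weight is the sum over copies. Logistic loss is used here (the task is
explicitly classification at this level), while the SNP level uses label
regression — both are recorded in the outputs.

Group scoring mirrors the SNP-level protocol for coherence: a single
seeded stratified 75/25 split, $\lambda$ chosen by inner 3-fold CV
maximising balanced accuracy (ties towards the sparser model), refit, and
balanced accuracy on the held-out quarter reported as the group's test
score, alongside the selected (nonzero-norm) pathways.

## Integration

Signatures are intersected at the gene level: SNP items contribute their
region's genes (both flanking genes for intergenic labels), pathway items
their member genes. The global signature ranks genes by the number of
distinct supporting analyses (level x task x dataset), ties broken by the
best per-analysis strength (gene p-value; `1 - selection frequency`;
`1 - test score`) and then lexicographically. Over-representation of a
gene list against gene sets uses the upper-tail hypergeometric test
(identical to one-sided Fisher's exact) with Benjamini-Hochberg
adjustment; the default universe is the set of genes mappable on the
platform's annotation, not the genome — the defensible null for chip-based
enrichment.

## The synthetic cohort generator

`simulate_gwas()` generates the statistical structure the analysis
assumes, so the whole pipeline is testable without access-controlled
cohort data: a Gaussian-threshold (copula) haplotype model with AR(1)
within-block latent correlation gives marginally Hardy-Weinberg SNPs with
block-wise LD; MAFs are uniform on a configurable range; a logistic
disease model with planted small-effect causal SNPs (and optionally one
APOE-like high-effect locus that can also determine the e4 carrier label,
mirroring platforms where APOE is genotyped on- or off-chip) produces the
diagnosis; missingness is completely at random; pseudo-genes, pathways
with controlled overlap, and pathway groups are built on top, with all
causal genes concentrated in one designated causal pathway. Everything is
driven by one mandatory seed, and `prevalence_intercept = NA` auto-centres
the linear predictor so the expected case fraction is one half.

What the generator does *not* emulate — population structure, relatedness,
batch effects, sex chromosomes, realistic LD decay, imputation artefacts —
bounds what green tests mean: they certify the statistical machinery
(calibration, recovery, reproducibility) under the stated model, not
robustness to confounding in real cohorts.

## Numerical and protocol choices

* Solver tolerances: `fit_l1l2` stops on relative objective change
  (default `1e-6` standalone; `1e-8` yields KKT residuals below `1e-4` on
  our fixtures); resampling configurations may relax to `1e-5` for speed,
  which we found does not change selected supports materially.
* All stochastic stages require an explicit integer seed; batch experiment
  $e$ uses `seed + e`, chromosomes and stages use disjoint seed offsets,
  and identical configuration yields bitwise-identical output files
  (checksummed in the pipeline manifest).
* Sign predictions break ties at 0 towards +1; CV ties prefer the sparser
  model; MAF orientation ties prefer the alphabetically earlier allele.
* Degenerate inputs are contracts, not crashes: an all-zero region gives
  (Q, p) = (0, 1); a zero-variance collapsed burden score gives p = 1; a
  task with fewer than two subjects per class is rejected; monomorphic
  SNPs are dropped and logged by the encoder.
* Problem sizes in the test-suite simulations (hundreds of subjects, tens
  to hundreds of SNPs, 15-50 experiments per batch, 2000-region null
  studies) were chosen as the smallest sizes at which the calibration and
  recovery properties are statistically decidable.

## Interfaces

All stages are exported R functions operating on plain files and in-memory
objects; `run_pipeline()` orchestrates encode, SNP scan, gene scan,
pathway scan and integration per task from a validated `pipeline_config()`
and writes a manifest with MD5 checksums of every output, so stages are
independently re-runnable and a rerun is verifiable. The on-disk formats
are deliberately minimal and text-based: PLINK text PED/MAP, a dosage TSV
triplet, a two-column SNP-to-region annotation TSV, standard GMT gene
sets, and a two-column pathway-group TSV.
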