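# Overlapping group lasso: design expansion, solver, path and scoring.

# a small deterministic setting: 2 pathways sharing one gene
make_overlap_fixture <- function(seed = 71, n = 60) {
  sim <- make_small_signal_sim(seed = seed, n = n, p = 30)
  enc <- encode_genotypes(sim$dataset)
  list(sim = sim, enc = enc)
}

test_that("latent duplication expands one column per (SNP, pathway) pair", {
  sim <- make_small_signal_sim(seed = 72, n = 40, p = 30)
  enc <- encode_genotypes(sim$dataset)
  ann <- sim$annotation
  # hand-built group: gene of SNPs 1..3 in both pathways
  gene <- ann$region_id[1]
  other <- ann$region_id[match(TRUE, ann$region_id != gene)]
  groups <- pathway_groups(
    groups = list(g1 = c("PA", "PB")),
    pathways = list(PA = c(gene, other), PB = gene))
  design <- build_group_design(enc, ann, groups, "g1")
  n_gene <- sum(ann$region_id == gene)
  n_other <- sum(ann$region_id == other)
  expect_equal(ncol(design$X), 2 * n_gene + n_other)
  expect_equal(unname(design$d), c(n_gene + n_other, n_gene))
  # expanded columns are copies of the encoded columns
  snp1 <- which(ann$region_id == gene)[1]
  copies <- which(design$snp_id == enc$snp_ids[snp1])
  expect_length(copies, 2)
  expect_equal(design$X[, copies[1]], design$X[, copies[2]],
               ignore_attr = TRUE)
})

test_that("disjoint pathways give a column permutation of the restriction", {
  sim <- make_small_signal_sim(seed = 73, n = 40, p = 30)
  enc <- encode_genotypes(sim$dataset)
  ann <- sim$annotation
  genes <- unique(ann$region_id)
  groups <- pathway_groups(
    groups = list(g1 = c("PA", "PB")),
    pathways = list(PA = genes[1], PB = genes[2]))
  design <- build_group_design(enc, ann, groups, "g1")
  keep <- ann$region_id %in% genes[1:2]
  expect_equal(sort(design$snp_id), sort(enc$snp_ids[keep]))
  expect_equal(ncol(design$X), sum(keep))
})

test_that("an empty design is a degenerate error", {
  sim <- make_small_signal_sim(seed = 74, n = 30, p = 12)
  enc <- encode_genotypes(sim$dataset)
  groups <- pathway_groups(groups = list(g1 = "PX"),
                           pathways = list(PX = "NOT_A_GENE"))
  expect_error(build_group_design(enc, sim$annotation, groups, "g1"),
               "no encoded SNP")
})

test_that("lambda above lambda_max zeroes every block", {
  fx <- make_overlap_fixture(seed = 75)
  labs <- make_task_labels(fx$sim$dataset, "cases_controls")
  X <- fx$enc$X[match(labs$subject_ids, rownames(fx$enc$X)), 1:12]
  block <- rep(c("b1", "b2", "b3"), each = 4)
  lmax <- group_lasso_lambda_max(X, labs$y, block)
  fit <- fit_overlap_group_lasso(X, labs$y, block, lambda = lmax * 1.001,
                                 tol = 1e-10, max_iter = 2000)
  expect_true(all(fit$v == 0))
  fit2 <- fit_overlap_group_lasso(X, labs$y, block, lambda = lmax * 0.8,
                                  tol = 1e-10, max_iter = 2000)
  expect_gt(max(fit2$block_norms), 0)
})

test_that("objective descends monotonically", {
  fx <- make_overlap_fixture(seed = 76)
  labs <- make_task_labels(fx$sim$dataset, "cases_controls")
  X <- fx$enc$X[match(labs$subject_ids, rownames(fx$enc$X)), 1:15]
  block <- rep(c("b1", "b2", "b3"), each = 5)
  lmax <- group_lasso_lambda_max(X, labs$y, block)
  for (lam in lmax * c(0.5, 0.1, 0.02)) {
    fit <- fit_overlap_group_lasso(X, labs$y, block, lam, tol = 1e-10,
                                   max_iter = 3000)
    expect_true(all(diff(fit$objective) <= 1e-12))
  }
})

test_that("disjoint-block fits match the BCD/BFGS group-lasso oracle", {
  withr::with_seed(77, {
    X <- matrix(rnorm(50 * 9), 50, 9)
    beta <- c(1.2, -0.8, 0.5, rep(0, 6))
    y <- ifelse(X %*% beta + rnorm(50, 0, 0.8) > 0, 1, -1)
  })
  block <- rep(c("b1", "b2", "b3"), each = 3)
  lmax <- group_lasso_lambda_max(X, y, block)
  for (lam in lmax * c(0.5, 0.2)) {
    fit <- fit_overlap_group_lasso(X, y, block, lam, tol = 1e-12,
                                   max_iter = 20000)
    o <- oracle_group_lasso_bcd(X, y, block, lam)
    J_fit <- oracle_group_lasso_objective(X, y, block, lam, fit$v,
                                          fit$intercept)
    expect_lt(abs(J_fit - o$objective), 1e-5)
  }
})

test_that("increasing lambda never adds selected blocks along a path", {
  withr::with_seed(78, {
    X <- matrix(rnorm(60 * 12), 60, 12)
    beta <- c(rep(1, 3), rep(0.4, 3), rep(0, 6))
    y <- ifelse(X %*% beta + rnorm(60) > 0, 1, -1)
  })
  block <- rep(paste0("b", 1:4), each = 3)
  fits <- group_lasso_path(X, y, block, n_lambda = 8, tol = 1e-9,
                           max_iter = 5000)
  n_sel <- vapply(fits, function(f) sum(f$block_norms > 1e-8), 0L)
  expect_true(all(diff(n_sel) >= 0))  # descending lambda: monotone growth
})

test_that("a shared SNP survives through the active copy (latent property)", {
  withr::with_seed(79, {
    Xs <- matrix(rnorm(50 * 4), 50, 4)
    y <- ifelse(Xs %*% c(1.5, 1.2, 0, 0) + rnorm(50, 0, 0.5) > 0, 1, -1)
  })
  # column 1 duplicated into both blocks (a gene in two pathways)
  X <- cbind(Xs[, 1], Xs[, 2], Xs[, 1], Xs[, 3], Xs[, 4])
  block <- c("b1", "b1", "b2", "b2", "b2")
  lmax <- group_lasso_lambda_max(X, y, block)
  # walk down the path to a lambda where exactly block b1 is active
  fits <- group_lasso_path(X, y, block, n_lambda = 12, tol = 1e-10,
                           max_iter = 5000)
  one_active <- Filter(function(f) {
    f$block_norms["b1"] > 0 && f$block_norms["b2"] == 0
  }, fits)
  expect_gt(length(one_active), 0)
  f <- one_active[[length(one_active)]]
  # the zeroed copy in b2 does not force the shared SNP's weight to zero:
  # its copy in the active block carries the signal
  expect_gt(abs(f$v[1]), 0)
  expect_equal(f$v[3], 0)
  expect_gt(abs(f$v[1] + f$v[3]), 0)  # effective (summed) SNP weight
})

test_that("score_group is deterministic and separable labels reach score 1", {
  sim <- make_small_signal_sim(seed = 80, n = 80, p = 30)
  enc <- encode_genotypes(sim$dataset)
  labs <- make_task_labels(sim$dataset, "apoe_e4")
  # label is determined by the APOE-like SNP; its pathway must win
  apoe_gene <- sim$annotation$region_id[
    match(sim$manifest$apoe_like_snp, sim$annotation$snp_id)]
  other_genes <- setdiff(unique(sim$annotation$region_id), apoe_gene)
  groups <- pathway_groups(
    groups = list(g1 = c("P_APOE", "P_NOISE")),
    pathways = list(P_APOE = apoe_gene, P_NOISE = other_genes[1:2]))
  design <- build_group_design(enc, sim$annotation, groups, "g1")
  s1 <- score_group(design, labs, seed = 17)
  s2 <- score_group(design, labs, seed = 17)
  expect_identical(s1, s2)
  expect_equal(s1$test_score, 1.0)
  expect_true("P_APOE" %in% s1$selected_pathways)
})
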