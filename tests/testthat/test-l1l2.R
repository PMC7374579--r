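# l1l2 elastic-net solver, classification metrics and the resampling batch.

test_that("tau at or above tau_max gives the exact zero solution", {
  X <- make_orthonormal_design(40, 6, seed = 41)
  y <- withr::with_seed(42, sample(c(1, -1), 40, replace = TRUE))
  tmax <- l1l2_tau_max(X, y)
  f <- fit_l1l2(X, y, tau = tmax, mu = 0.01, tol = 1e-10)
  expect_identical(f$w, numeric(6))
  f2 <- fit_l1l2(X, y, tau = 2 * tmax, mu = 0.01, tol = 1e-10)
  expect_identical(f2$w, numeric(6))
  # just below tau_max at least one coordinate activates
  f3 <- fit_l1l2(X, y, tau = 0.95 * tmax, mu = 0, tol = 1e-12,
                 max_iter = 5000)
  expect_gt(sum(f3$w != 0), 0)
})

test_that("orthonormal designs reproduce the soft-threshold closed form", {
  n <- 50
  X <- make_orthonormal_design(n, 10, seed = 43)
  y <- withr::with_seed(44, rnorm(n))
  y <- y - mean(y)
  for (tau in c(0.02, 0.1, 0.4)) {
    for (mu in c(0, 0.05, 0.5)) {
      f <- fit_l1l2(X, y, tau, mu, tol = 1e-13, max_iter = 10000,
                    fit_intercept = FALSE)
      corr <- as.vector(crossprod(X, y)) / n
      closed <- sign(corr) * pmax(abs(corr) - tau / 2, 0) / (1 + mu)
      expect_lt(max(abs(f$w - closed)), 1e-6)
    }
  }
})

test_that("solver matches an independent coordinate-descent oracle", {
  withr::with_seed(45, {
    X <- matrix(rnorm(10 * 3), 10, 3)
    y <- sample(c(1, -1), 10, replace = TRUE)
  })
  for (tau in c(0.05, 0.3)) {
    f <- fit_l1l2(X, y, tau, mu = 0.01, tol = 1e-14, max_iter = 50000)
    o <- oracle_l1l2_cd(X, y, tau, mu = 0.01)
    J_f <- oracle_l1l2_objective(X, y, f$w, f$intercept, tau, 0.01)
    expect_lt(abs(J_f - o$objective), 1e-6)
  }
})

test_that("objective descends monotonically and satisfies KKT conditions", {
  withr::with_seed(46, {
    X <- matrix(rnorm(60 * 25), 60, 25)
    y <- sample(c(1, -1), 60, replace = TRUE)
  })
  for (tau in c(0.01, 0.1, 0.5)) {
    f <- fit_l1l2(X, y, tau, mu = 0.01, tol = 1e-10, max_iter = 20000)
    expect_true(all(diff(f$objective) <= 1e-12))
    expect_lt(l1l2_kkt_residual(X, y, f), 1e-4)
  }
})

test_that("support is monotone in tau on an orthonormal design", {
  n <- 60
  X <- make_orthonormal_design(n, 12, seed = 47)
  y <- withr::with_seed(48, rnorm(n))
  grid <- l1l2_tau_grid(X, y, n_tau = 12)
  fits <- fit_l1l2_path(X, y, grid, mu = 0.01, tol = 1e-12)
  supports <- lapply(fits, function(f) which(f$w != 0))
  for (k in 2:length(supports)) {
    # grid is descending: smaller tau can only add features
    expect_true(all(supports[[k - 1]] %in% supports[[k]]))
  }
})

test_that("mu = 0, tau -> 0 recovers the least-squares fit", {
  withr::with_seed(49, {
    X <- matrix(rnorm(80 * 5), 80, 5)
    y <- rnorm(80)
  })
  f <- fit_l1l2(X, y, tau = 1e-8, mu = 0, tol = 1e-14, max_iter = 100000)
  ls <- stats::lm.fit(cbind(1, X), y)$coefficients
  expect_lt(max(abs(f$w - ls[-1])), 1e-4)
  expect_lt(abs(f$intercept - ls[1]), 1e-4)
})

test_that("balanced accuracy and MCC follow their definitions", {
  y <- c(1, 1, -1, -1)
  expect_equal(balanced_accuracy(y, y), 1.0)
  expect_equal(mcc(y, y), 1.0)
  # all-positive prediction: degenerate denominator -> MCC 0
  expect_equal(mcc(y, rep(1, 4)), 0)
  expect_equal(balanced_accuracy(y, rep(1, 4)), 0.5)
  # confusion (TP, FN, TN, FP) = (8, 2, 6, 4)
  y_true <- c(rep(1, 10), rep(-1, 10))
  y_pred <- c(rep(1, 8), rep(-1, 2), rep(-1, 6), rep(1, 4))
  expect_equal(balanced_accuracy(y_true, y_pred), 0.7)
  expect_equal(mcc(y_true, y_pred), 40 / sqrt(9600))
  expect_error(balanced_accuracy(numeric(0), numeric(0)), "empty")
  expect_error(mcc(c(1, -1), c(1, 0)), "labels")
})

test_that("run_batch is deterministic and respects the permutation contract", {
  sim <- make_small_signal_sim(seed = 51, n = 80, p = 20)
  labs <- make_task_labels(sim$dataset, "cases_controls")
  enc <- encode_genotypes(sim$dataset, subjects = labs$subject_ids)
  ec <- elastic_net_config(tau_grid = NULL, mu = 0.01, tol = 1e-5,
                           max_iter = 300)
  rc <- resampling_config(n_regular = 5, n_permutation = 5,
                          test_fraction = 0.25, inner_folds = 3, seed = 7)
  b1 <- run_batch(enc$X, labs$y, enc$snp_ids, ec, rc)
  b2 <- run_batch(enc$X, labs$y, enc$snp_ids, ec, rc)
  expect_identical(b1, b2)
  perm <- run_batch(enc$X, labs$y, enc$snp_ids, ec, rc, permute = TRUE)
  expect_false(perm$permuted == b1$permuted)
  expect_equal(nrow(perm$records), 5)
  expect_true(all(perm$records$bal_acc >= 0 & perm$records$bal_acc <= 1))
  expect_true(all(abs(perm$records$mcc) <= 1))
})

test_that("infeasible stratification is a config error before any run", {
  y <- c(rep(1, 4), rep(-1, 40))
  X <- matrix(rnorm(44 * 5), 44, 5)
  rc <- resampling_config(n_regular = 2, n_permutation = 2,
                          test_fraction = 0.25, inner_folds = 5, seed = 1)
  expect_error(run_batch(X, y, paste0("s", 1:5),
                         elastic_net_config(), rc),
               "infeasible stratification")
})

test_that("signature with threshold 1 is contained in every selected set", {
  sim <- make_small_signal_sim(seed = 52, n = 80, p = 20)
  labs <- make_task_labels(sim$dataset, "cases_controls")
  enc <- encode_genotypes(sim$dataset, subjects = labs$subject_ids)
  ec <- elastic_net_config(tol = 1e-5, max_iter = 300)
  rc <- resampling_config(n_regular = 6, n_permutation = 4,
                          selection_threshold = 1.0, seed = 9)
  reg <- run_batch(enc$X, labs$y, enc$snp_ids, ec, rc)
  perm <- run_batch(enc$X, labs$y, enc$snp_ids, ec, rc, permute = TRUE)
  res <- summarize_chromosome(reg, perm, rc, chromosome = "1")
  for (sel in reg$selected) {
    expect_true(all(res$signature %in% sel))
  }
})

test_that("identical regular and permutation distributions are not reliable", {
  sim <- make_small_signal_sim(seed = 53, n = 80, p = 20)
  labs <- make_task_labels(sim$dataset, "cases_controls")
  enc <- encode_genotypes(sim$dataset, subjects = labs$subject_ids)
  ec <- elastic_net_config(tol = 1e-5, max_iter = 300)
  rc <- resampling_config(n_regular = 5, n_permutation = 5, seed = 3)
  reg <- run_batch(enc$X, labs$y, enc$snp_ids, ec, rc)
  res <- summarize_chromosome(reg, reg, rc, chromosome = "1")
  expect_equal(res$mean_difference, 0)
  expect_false(res$reliable)
})
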