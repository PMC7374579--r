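# Burden, SKAT and SKAT-O region tests and the gene scan.

test_that("intercept-only null model has closed-form residuals", {
  null <- fit_null(c(1, 1, 0, 0))
  expect_equal(null$mu0, 0.5)
  expect_equal(null$residuals, c(0.5, 0.5, -0.5, -0.5))
  expect_equal(fit_null(c(1, 0, 0, 0))$mu0, 0.25)
  withr::with_seed(61, {
    y <- rbinom(50, 1, 0.3)
    if (sum(y) %in% c(0, 50)) y[1] <- 1 - y[1]
    expect_lt(abs(sum(fit_null(y)$residuals)), 1e-9)
  })
  expect_error(fit_null(rep(1, 5)), "degenerate")
})

test_that("an all-zero region gives Q = 0, p = 1", {
  null <- fit_null(rep(c(1, 0), 10))
  res <- skat_test(matrix(0L, 20, 3), null)
  expect_equal(res$Q, 0)
  expect_equal(res$p, 1)
  expect_equal(burden_test(matrix(0L, 20, 3), null)$p, 1)
})

test_that("duplicating every SNP column exactly doubles Q", {
  withr::with_seed(62, {
    G <- sapply(c(0.2, 0.35), function(p) rbinom(30, 2, p))
    y <- rbinom(30, 1, 0.5)
    if (sum(y) %in% c(0, 30)) y[1] <- 1 - y[1]
  })
  null <- fit_null(y)
  w <- c(1.3, 0.7)
  q1 <- skat_test(G, null, weights = w)$Q
  q2 <- skat_test(cbind(G, G), null, weights = c(w, w))$Q
  expect_equal(q2, 2 * q1, tolerance = 1e-12)
})

test_that("single-SNP burden equals the single-SNP score test exactly", {
  withr::with_seed(63, {
    g <- rbinom(40, 2, 0.3)
    y <- rbinom(40, 1, 0.5)
    if (sum(y) %in% c(0, 40)) y[1] <- 1 - y[1]
  })
  null <- fit_null(y)
  b <- burden_test(matrix(g, ncol = 1), null, weights = 2.5)
  s <- single_snp_score_p(matrix(g, ncol = 1), null)
  expect_equal(b$p, s)
  # and SKAT of one SNP with the same weight agrees (1-D equivalence)
  sk <- skat_test(matrix(g, ncol = 1), null, weights = 2.5)
  expect_equal(sk$Q, b$Q * 1, tolerance = 1e-12)
  expect_equal(sk$p, b$p, tolerance = 1e-10)
})

test_that("two perfectly correlated SNPs collapse to the single-SNP test", {
  withr::with_seed(64, {
    g <- rbinom(50, 2, 0.25)
    y <- rbinom(50, 1, 0.4)
    if (sum(y) %in% c(0, 50)) y[1] <- 1 - y[1]
  })
  null <- fit_null(y)
  p_pair <- burden_test(cbind(g, g), null, weights = c(1, 1))$p
  p_single <- burden_test(matrix(g, ncol = 1), null, weights = 1)$p
  expect_equal(p_pair, p_single, tolerance = 1e-12)
})

test_that("SKAT p is invariant to subject and SNP reordering", {
  withr::with_seed(65, {
    G <- sapply(c(0.15, 0.3, 0.45), function(p) rbinom(40, 2, p))
    y <- rbinom(40, 1, 0.5)
    if (sum(y) %in% c(0, 40)) y[1] <- 1 - y[1]
    perm <- sample(40)
  })
  null <- fit_null(y)
  w <- beta_maf_weights(colMeans(G) / 2)
  p0 <- skat_test(G, null, weights = w)$p
  p_subj <- skat_test(G[perm, ], fit_null(y[perm]), weights = w)$p
  expect_equal(p_subj, p0, tolerance = 1e-9)
  p_cols <- skat_test(G[, 3:1], null, weights = w[3:1])$p
  expect_equal(p_cols, p0, tolerance = 1e-9)
})

test_that("SKAT-O endpoints reproduce SKAT and burden exactly", {
  withr::with_seed(66, {
    G <- sapply(c(0.2, 0.3, 0.4), function(p) rbinom(60, 2, p))
    y <- rbinom(60, 1, 0.5)
    if (sum(y) %in% c(0, 60)) y[1] <- 1 - y[1]
  })
  null <- fit_null(y)
  w <- beta_maf_weights(colMeans(G) / 2)
  expect_equal(skato_test(G, null, w, rho_grid = 0)$p,
               skat_test(G, null, w)$p)
  expect_equal(skato_test(G, null, w, rho_grid = 1)$p,
               burden_test(G, null, w)$p)
  # min-p Bonferroni over {0, 0.5, 1} is bounded by [min_p, 3 min_p]
  so <- skato_test(G, null, w, rho_grid = c(0, 0.5, 1),
                   method = "minp-bonferroni")
  expect_gte(so$p, min(so$p_rho))
  expect_lte(so$p, min(1, 3 * min(so$p_rho)))
  # the optimal combination obeys the same bounds
  so2 <- skato_test(G, null, w, rho_grid = c(0, 0.5, 1))
  expect_gte(so2$p, min(so2$p_rho))
  expect_lte(so2$p, min(1, 3 * min(so2$p_rho)))
})

test_that("Davies and Liu-Lee tail routes agree within 10 percent", {
  withr::with_seed(67, {
    for (rep in 1:20) {
      lam <- sort(rexp(sample(2:8, 1)), decreasing = TRUE)
      q <- sum(lam) * runif(1, 0.5, 6)
      p_d <- pchisq_mixture(q, lam, method = "davies")$p
      p_l <- pchisq_mixture(q, lam, method = "liu")$p
      if (p_d >= 1e-4 && p_d <= 0.99) {
        expect_lt(abs(p_d - p_l) / p_d, 0.10)
      }
    }
  })
})

test_that("the Bonferroni threshold rule reproduces the region-count form", {
  expect_equal(bonferroni_threshold(36496), 0.05 / 36496)
  expect_equal(bonferroni_threshold(10, alpha = 0.01), 0.001)
  expect_error(bonferroni_threshold(0), "n_regions")
})

test_that("the gene scan groups by region, sorts by SKAT p and flags", {
  sim <- make_small_signal_sim(seed = 68, n = 150, p = 30)
  labs <- make_task_labels(sim$dataset, "apoe_e4")
  gs <- run_gene_scan(sim$dataset, sim$annotation, labs, threshold = 0.05)
  expect_s3_class(gs, "gene_scan")
  expect_false(is.unsorted(gs$p_skat))
  expect_true(all(gs$p_skat > 0 & gs$p_skat <= 1))
  expect_true(all(gs$q_skat >= 0))
  expect_equal(gs$sig_skat, gs$p_skat < attr(gs, "threshold"))
  expect_true(all(gs$top_snp %in% sim$dataset$snp_ids))
  expect_equal(sum(gs$n_snps), 30)  # every SNP mapped in the simulation
  # bonferroni mode derives the threshold from the region count
  gs2 <- run_gene_scan(sim$dataset, sim$annotation, labs)
  expect_equal(attr(gs2, "threshold"), 0.05 / nrow(gs2))
  # with flat weights the APOE-driving locus makes its gene the top region
  # (Beta(1,25) weights would down-weight this common variant)
  gs_flat <- run_gene_scan(sim$dataset, sim$annotation, labs,
                           threshold = 0.05, weights_beta = c(1, 1))
  apoe_gene <- sim$annotation$region_id[
    match(sim$manifest$apoe_like_snp, sim$annotation$snp_id)]
  expect_equal(gs_flat$region_id[1], apoe_gene)
  expect_equal(gs_flat$top_snp[1], sim$manifest$apoe_like_snp)
})
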