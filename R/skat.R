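# Region-based association tests on raw minor-allele counts: weighted
# burden (1-df score test of the collapsed genotype), SKAT (variance
# component score test, mixture-of-chi-squares null) and SKAT-O (optimal
# convex combination over a rho grid). No covariates: the null model is an
# intercept-only logistic fit.

#' Fit the intercept-only logistic null model
#'
#' With no covariates the fitted case probability under the null is the
#' sample case fraction for every subject; residuals are `y - mu0` and the
#' variance weight is `mu0 (1 - mu0)`.
#'
#' @param y01 0/1 phenotype vector (both classes present).
#' @return a `skat_null` list: `mu0`, `residuals`, `v`, `n`.
#' @export
fit_null <- function(y01) {
  if (!all(y01 %in% c(0, 1))) stop_format("y01 must be 0/1")
  mu0 <- mean(y01)
  if (mu0 <= 0 || mu0 >= 1) {
    stop_format("degenerate null: only one class present")
  }
  structure(list(mu0 = mu0, residuals = y01 - mu0, v = mu0 * (1 - mu0),
                 n = length(y01)),
            class = "skat_null")
}

#' Beta(1, 25) variant weights from minor-allele frequencies
#'
#' The SKAT-convention weighting: `w_j = dbeta(MAF_j, 1, 25)`, up-weighting
#' rare variants.
#'
#' @param maf numeric vector of minor-allele frequencies.
#' @param shape1,shape2 Beta density parameters.
#' @return numeric weight vector.
#' @export
beta_maf_weights <- function(maf, shape1 = 1, shape2 = 25) {
  stats::dbeta(maf, shape1, shape2)
}

# mean-impute missing calls and return the region matrix with its MAFs
prepare_region <- function(G_region) {
  G <- as.matrix(G_region)
  storage.mode(G) <- "double"
  maf <- colMeans(G, na.rm = TRUE) / 2
  maf[is.nan(maf)] <- 0
  na_idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(na_idx)) G[na_idx] <- 2 * maf[na_idx[, 2]]
  list(G = G, maf = maf)
}

# centered weighted genotype matrix scaled so crossprod gives the null
# covariance of the score vector z = (GW)'r
null_score_design <- function(G, weights, null) {
  GW <- sweep(G, 2, weights, "*")
  sqrt(null$v) * sweep(GW, 2, colMeans(GW))
}

#' SKAT variance-component score test of a SNP region
#'
#' `Q = r' G W^2 G' r` with `W = diag(w_j)`; under the null `Q` is a mixture
#' `sum_k lambda_k chi2_1` with `lambda_k` the eigenvalues of
#' `W G' P0 G W`, `P0 = diag(v) - v v' / sum(v)`. The tail probability is
#' evaluated by characteristic-function inversion with a Liu-Lee
#' moment-matching fallback (flagged in the result). Missing genotypes are
#' mean-imputed; an all-zero region gives `(Q, p) = (0, 1)`.
#'
#' @param G_region genotype submatrix (subjects x region SNPs, counts 0/1/2
#'   with `NA` allowed).
#' @param null a `skat_null` from [fit_null()].
#' @param weights per-SNP weights; default Beta(1, 25) density at the MAF.
#' @return list with `Q`, `p`, `method` (p-value route), `lambda`,
#'   `weights`.
#' @export
skat_test <- function(G_region, null, weights = NULL) {
  prep <- prepare_region(G_region)
  G <- prep$G
  if (nrow(G) != null$n) stop_format("region and null model sizes differ")
  w <- weights %||% beta_maf_weights(prep$maf)
  z <- as.vector(crossprod(sweep(G, 2, w, "*"), null$residuals))
  Q <- sum(z^2)
  Z1 <- null_score_design(G, w, null)
  lambda <- eigen(crossprod(Z1), symmetric = TRUE, only.values = TRUE)$values
  res <- pchisq_mixture(Q, lambda)
  list(Q = Q, p = res$p, method = res$method, lambda = lambda, weights = w)
}

#' Weighted burden score test of a SNP region
#'
#' Collapses the region into one weighted score per subject,
#' `s_i = sum_j w_j g_ij`, and applies the 1-df score test of `s` in the
#' intercept-only logistic null: `Q_B = (s' r)^2`, variance `s' P0 s`,
#' `p = P[chi2_1 > Q_B / var]`. A zero-variance collapsed score gives
#' `p = 1`.
#'
#' @inheritParams skat_test
#' @return list with `Q`, `p`, `weights`.
#' @export
burden_test <- function(G_region, null, weights = NULL) {
  prep <- prepare_region(G_region)
  G <- prep$G
  if (nrow(G) != null$n) stop_format("region and null model sizes differ")
  w <- weights %||% beta_maf_weights(prep$maf)
  s <- as.vector(G %*% w)
  score <- sum(s * null$residuals)
  v_s <- null$v * (sum(s^2) - null$n * mean(s)^2)
  Q <- score^2
  if (v_s <= 1e-12) return(list(Q = Q, p = 1, weights = w))
  list(Q = Q, p = clamp_p(stats::pchisq(Q / v_s, df = 1, lower.tail = FALSE)),
       weights = w)
}

#' SKAT-O: optimal combination of SKAT and burden over a rho grid
#'
#' Evaluates `Q_rho = (1 - rho) Q_SKAT + rho Q_B` on the common score vector
#' for every `rho` in the grid and combines the per-rho p-values. Two
#' combination rules are available:
#' \describe{
#'   \item{`"optimal"`}{the minimum-p statistic is referred to its exact
#'     asymptotic null via the one-dimensional integral over the common
#'     1-df component (the SKAT-O construction), which preserves the test's
#'     size under correlation of the per-rho statistics.}
#'   \item{`"minp-bonferroni"`}{`min(1, |grid| * min_rho p_rho)` -- simpler
#'     and conservative.}
#' }
#' A singleton grid returns the corresponding per-rho p-value directly, so
#' `rho_grid = 0` reproduces [skat_test()] and `rho_grid = 1` reproduces
#' [burden_test()] exactly.
#'
#' @inheritParams skat_test
#' @param rho_grid values in `[0, 1]`; the default spans SKAT (`rho = 0`)
#'   to burden (`rho = 1`). A multi-point grid must contain both endpoints.
#' @param method combination rule (see above).
#' @return list with `p`, `p_rho` (named per-rho p-values), `rho_min`,
#'   `Q_rho`, `method` (rule actually used).
#' @export
skato_test <- function(G_region, null, weights = NULL,
                       rho_grid = c(0, 0.01, 0.04, 0.09, 0.25, 0.5, 1),
                       method = c("optimal", "minp-bonferroni")) {
  method <- match.arg(method)
  rho_grid <- sort(unique(rho_grid))
  if (any(rho_grid < 0 | rho_grid > 1)) {
    stop_format("rho_grid must lie in [0, 1]")
  }
  if (length(rho_grid) > 1 && !(0 %in% rho_grid && 1 %in% rho_grid)) {
    stop_format("a multi-point rho_grid must contain 0 and 1")
  }
  prep <- prepare_region(G_region)
  G <- prep$G
  if (nrow(G) != null$n) stop_format("region and null model sizes differ")
  w <- weights %||% beta_maf_weights(prep$maf)
  k <- ncol(G)
  z <- as.vector(crossprod(sweep(G, 2, w, "*"), null$residuals))
  Q_S <- sum(z^2)
  Q_B <- sum(z)^2
  Q_rho <- (1 - rho_grid) * Q_S + rho_grid * Q_B
  names(Q_rho) <- rho_grid

  Z1 <- null_score_design(G, w, null)
  Sigma <- crossprod(Z1)
  lambda_rho <- vector("list", length(rho_grid))
  p_rho <- numeric(length(rho_grid))
  for (i in seq_along(rho_grid)) {
    rho <- rho_grid[i]
    if (rho == 1) {
      # rank-1 combination: exact scaled chi-square = burden score test
      lam <- sum(Sigma)
      lambda_rho[[i]] <- lam
      p_rho[i] <- if (lam <= 1e-12) 1 else
        clamp_p(stats::pchisq(Q_B / lam, df = 1, lower.tail = FALSE))
    } else {
      R_sqrt <- diag(sqrt(1 - rho), k) +
        matrix((sqrt(1 - rho + k * rho) - sqrt(1 - rho)) / k, k, k)
      lam <- eigen(R_sqrt %*% Sigma %*% R_sqrt, symmetric = TRUE,
                   only.values = TRUE)$values
      lambda_rho[[i]] <- lam
      p_rho[i] <- pchisq_mixture(Q_rho[i], lam)$p
    }
  }
  names(p_rho) <- rho_grid
  T_min <- min(p_rho)
  rho_min <- rho_grid[which.min(p_rho)]
  if (length(rho_grid) == 1L) {
    return(list(p = T_min, p_rho = p_rho, rho_min = rho_min, Q_rho = Q_rho,
                method = "single-rho"))
  }
  if (method == "minp-bonferroni") {
    return(list(p = min(1, length(rho_grid) * T_min), p_rho = p_rho,
                rho_min = rho_min, Q_rho = Q_rho, method = "minp-bonferroni"))
  }
  p <- skato_optimal_p(T_min, rho_grid, lambda_rho, Z1)
  if (is.na(p)) {
    p <- min(1, length(rho_grid) * T_min)
    return(list(p = p, p_rho = p_rho, rho_min = rho_min, Q_rho = Q_rho,
                method = "minp-bonferroni"))
  }
  # theoretical bounds of the min-p statistic's tail probability
  p <- min(max(p, T_min), min(1, length(rho_grid) * T_min))
  list(p = p, p_rho = p_rho, rho_min = rho_min, Q_rho = Q_rho,
       method = "optimal")
}

# Exact asymptotic tail of the minimum-p combination (the SKAT-O one-
# dimensional integration): condition on the shared 1-df component eta0
# carried by the column-mean direction of the score design and integrate
# the remainder's mixture-of-chi-squares distribution.
skato_optimal_p <- function(T_min, rho_grid, lambda_rho, Z1) {
  k <- ncol(Z1)
  z_mean <- rowMeans(Z1)
  Zms <- sum(z_mean^2)
  if (Zms <= 1e-12) return(NA_real_)
  cof <- as.vector(crossprod(Z1, z_mean)) / Zms
  Z2 <- Z1 - outer(z_mean, cof)
  M2 <- crossprod(Z2)
  lam <- eigen(M2, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam, 0) * 1e-10]
  if (!length(lam)) return(NA_real_)
  var_zeta <- 4 * Zms * as.numeric(t(cof) %*% M2 %*% cof)
  mu_kappa <- sum(lam)
  var_kappa <- 2 * sum(lam^2) + var_zeta
  tau_rho <- Zms * ((1 - rho_grid) * sum(cof^2) + rho_grid * k^2)
  # per-rho thresholds at tail probability T_min
  q_rho <- vapply(seq_along(rho_grid), function(i) {
    l <- lambda_rho[[i]]
    l <- l[l > max(l, 0) * 1e-10]
    if (length(l) == 1L) {
      l * stats::qchisq(T_min, df = 1, lower.tail = FALSE)
    } else {
      liu_lee_quantile(T_min, l)
    }
  }, 0)
  one_minus_rho <- pmax(1 - rho_grid, 1e-3)  # cap rho = 1 for the division
  shrink <- sqrt(max(var_kappa - var_zeta, 0) / var_kappa)
  # inner distribution of the remainder kappa via the Liu-Lee closed form
  # (moment-matched chi-square), keeping the integrand cheap; the per-rho
  # p-values feeding T_min retain the characteristic-function route
  integrand <- function(x) {
    vapply(x, function(xi) {
      c_min <- min((q_rho - tau_rho * xi) / one_minus_rho)
      if (c_min <= 0) return(0)
      c_adj <- (c_min - mu_kappa) * shrink + mu_kappa
      if (c_adj <= 0) return(0)
      F_kappa <- 1 - liu_lee_upper(c_adj, lam)
      F_kappa * stats::dchisq(xi, df = 1)
    }, 0)
  }
  val <- tryCatch(
    stats::integrate(integrand, 0, 40, subdivisions = 200L,
                     rel.tol = 1e-6, stop.on.error = FALSE),
    error = function(e) NULL)
  if (is.null(val) || !is.finite(val$value)) return(NA_real_)
  1 - val$value
}

#' Single-SNP score-test p-values
#'
#' The 1-df score test of each genotype column in the intercept-only
#' logistic null (equivalently [burden_test()] of a one-SNP region with
#' unit weight); used to report the top SNP of a significant region.
#'
#' @param G genotype matrix (counts, `NA` allowed).
#' @param null a `skat_null`.
#' @return numeric vector of p-values, one per column.
#' @export
single_snp_score_p <- function(G, null) {
  prep <- prepare_region(G)
  vapply(seq_len(ncol(prep$G)), function(j) {
    burden_test(prep$G[, j, drop = FALSE], null, weights = 1)$p
  }, 0)
}

#' Genome-wide Bonferroni significance threshold
#'
#' The conservative region-count rule `alpha / n_regions` used to declare a
#' gene genome-wide significant.
#'
#' @param n_regions number of tested regions.
#' @param alpha family-wise error rate.
#' @return the per-region threshold.
#' @export
bonferroni_threshold <- function(n_regions, alpha = 0.05) {
  if (n_regions < 1) stop_format("n_regions must be >= 1")
  alpha / n_regions
}

#' Region-based gene scan over an annotated dataset
#'
#' Groups SNPs by their annotated region (gene or intergenic label), runs
#' burden, SKAT and SKAT-O on the raw minor-allele counts of every region
#' (the tests operate on genotypes, not on the continuous encoding), and
#' applies a genome-wide significance threshold: either
#' `"bonferroni"` (`0.05 / n_regions`) or a fixed numeric value. SNPs with
#' region `"UNMAPPED"` are excluded. Results are sorted by ascending SKAT
#' p-value; every region also reports its top SNP (smallest single-SNP
#' score-test p-value).
#'
#' @param ds a [genotype_dataset()].
#' @param annotation a `snp_annotation` covering the dataset's SNPs.
#' @param labels a `task_labels`; the scan is restricted to its subjects.
#' @param threshold `"bonferroni"` or a numeric threshold.
#' @param weights_beta Beta parameters of the MAF weights.
#' @param rho_grid,skato_method passed to [skato_test()].
#' @return a `gene_scan` data frame (columns `region_id`, `chrom`,
#'   `n_snps`, `q_skat`, `p_burden`, `p_skat`, `p_skato`, `sig_burden`,
#'   `sig_skat`, `sig_skato`, `top_snp`) with attributes `threshold` and
#'   `n_regions`.
#' @export
run_gene_scan <- function(ds, annotation, labels, threshold = "bonferroni",
                          weights_beta = c(1, 25),
                          rho_grid = c(0, 0.01, 0.04, 0.09, 0.25, 0.5, 1),
                          skato_method = "optimal") {
  ds <- subset_dataset(ds, subjects = labels$subject_ids)
  y01 <- (labels$y + 1) / 2
  null <- fit_null(y01)
  region_of <- annotation$region_id[match(ds$snp_ids, annotation$snp_id)]
  region_of[is.na(region_of)] <- "UNMAPPED"
  mapped <- region_of != "UNMAPPED"
  if (!any(mapped)) stop_format("no SNP maps to a region")
  regions <- unique(region_of[mapped])
  rows <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    cols <- which(region_of == regions[i])
    Gr <- ds$G[, cols, drop = FALSE]
    maf <- prepare_region(Gr)$maf
    w <- beta_maf_weights(maf, weights_beta[1], weights_beta[2])
    sk <- skat_test(Gr, null, weights = w)
    bu <- burden_test(Gr, null, weights = w)
    so <- skato_test(Gr, null, weights = w, rho_grid = rho_grid,
                     method = skato_method)
    snp_p <- single_snp_score_p(Gr, null)
    rows[[i]] <- data.frame(
      region_id = regions[i],
      chrom = ds$chrom[cols[1]],
      n_snps = length(cols),
      q_skat = sk$Q,
      p_burden = bu$p,
      p_skat = sk$p,
      p_skato = so$p,
      top_snp = ds$snp_ids[cols[which.min(snp_p)]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  thr <- if (identical(threshold, "bonferroni")) {
    bonferroni_threshold(nrow(out))
  } else {
    as.numeric(threshold)
  }
  out$sig_burden <- out$p_burden < thr
  out$sig_skat <- out$p_skat < thr
  out$sig_skato <- out$p_skato < thr
  out <- out[order(out$p_skat, out$region_id), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "n_regions") <- nrow(out)
  class(out) <- c("gene_scan", "data.frame")
  out
}
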