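# Independent reference implementations used as oracles in tests. These
# deliberately use different algorithms than the package (coordinate
# descent instead of proximal gradient; BFGS block minimisation instead of
# block soft-thresholding) so agreement is evidence of correctness.

# Coordinate-descent solver of the l1l2 objective
#   J(w, b) = mean((y - Xw - b)^2) + mu ||w||^2 + tau ||w||_1
oracle_l1l2_cd <- function(X, y, tau, mu, fit_intercept = TRUE,
                           sweeps = 2000, tol = 1e-12) {
  n <- nrow(X)
  p <- ncol(X)
  w <- numeric(p)
  b <- if (fit_intercept) mean(y) else 0
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  col_ss <- colSums(X^2)
  obj <- function(w, b) {
    mean((y - X %*% w - b)^2) + mu * sum(w^2) + tau * sum(abs(w))
  }
  J <- obj(w, b)
  for (s in seq_len(sweeps)) {
    for (j in seq_len(p)) {
      r_j <- y - b - X[, -j, drop = FALSE] %*% w[-j]
      num <- soft(2 / n * sum(X[, j] * r_j), tau)
      w[j] <- num / (2 / n * col_ss[j] + 2 * mu)
    }
    if (fit_intercept) b <- mean(y - X %*% w)
    J_new <- obj(w, b)
    if (abs(J - J_new) <= tol * max(1, abs(J))) break
    J <- J_new
  }
  list(w = w, intercept = b, objective = obj(w, b))
}

oracle_l1l2_objective <- function(X, y, w, b, tau, mu) {
  mean((y - X %*% w - b)^2) + mu * sum(w^2) + tau * sum(abs(w))
}

# Block coordinate descent for the standard (non-overlapping) group lasso
# with logistic loss. Each block is either set to zero (subgradient test)
# or minimised by BFGS from a nonzero start, where the objective is smooth.
oracle_group_lasso_bcd <- function(X, y, block, lambda, intercept_start = 0,
                                   sweeps = 200, tol = 1e-10) {
  n <- nrow(X)
  block <- factor(block, levels = unique(as.character(block)))
  idx <- split(seq_len(ncol(X)), block)
  sqrt_d <- sqrt(lengths(idx))
  v <- numeric(ncol(X))
  b <- intercept_start
  loss <- function(eta) mean(log1p(exp(-y * eta)))
  full_obj <- function(v, b) {
    loss(as.vector(X %*% v) + b) +
      lambda * sum(sqrt_d * vapply(idx, function(i) sqrt(sum(v[i]^2)), 0))
  }
  J <- full_obj(v, b)
  for (s in seq_len(sweeps)) {
    # intercept: 1-d Newton steps
    for (r in 1:25) {
      eta <- as.vector(X %*% v) + b
      p_ <- stats::plogis(-y * eta)
      g <- mean(-y * p_)
      h <- mean(p_ * (1 - p_))
      if (h < 1e-12) break
      b <- b - g / h
      if (abs(g) < 1e-12) break
    }
    for (g_i in seq_along(idx)) {
      cols <- idx[[g_i]]
      eta_rest <- as.vector(X[, -cols, drop = FALSE] %*% v[-cols]) + b
      Xg <- X[, cols, drop = FALSE]
      # zero-block optimality: ||grad_g loss(0)|| <= lambda sqrt(d_g)
      p0 <- stats::plogis(-y * eta_rest)
      grad0 <- as.vector(crossprod(Xg, -y * p0)) / n
      if (sqrt(sum(grad0^2)) <= lambda * sqrt_d[g_i] + 1e-12) {
        v[cols] <- 0
        next
      }
      fn <- function(vg) {
        loss(eta_rest + as.vector(Xg %*% vg)) +
          lambda * sqrt_d[g_i] * sqrt(sum(vg^2))
      }
      gr <- function(vg) {
        eta <- eta_rest + as.vector(Xg %*% vg)
        p_ <- stats::plogis(-y * eta)
        nrm <- sqrt(sum(vg^2))
        as.vector(crossprod(Xg, -y * p_)) / n +
          lambda * sqrt_d[g_i] * vg / max(nrm, 1e-12)
      }
      start <- v[cols]
      if (all(start == 0)) start <- -grad0 * 1e-2  # descend off the kink
      opt <- stats::optim(start, fn, gr, method = "BFGS",
                          control = list(maxit = 200, reltol = 1e-14))
      v[cols] <- opt$par
    }
    J_new <- full_obj(v, b)
    if (abs(J - J_new) <= tol * max(1, abs(J))) break
    J <- J_new
  }
  list(v = v, intercept = b, objective = full_obj(v, b))
}

oracle_group_lasso_objective <- function(X, y, block, lambda, v, b) {
  block <- factor(block, levels = unique(as.character(block)))
  idx <- split(seq_len(ncol(X)), block)
  sqrt_d <- sqrt(lengths(idx))
  mean(log1p(exp(-y * (as.vector(X %*% v) + b)))) +
    lambda * sum(sqrt_d * vapply(idx, function(i) sqrt(sum(v[i]^2)), 0))
}

# Exhaustive label-permutation p-value of the SKAT statistic: permutes the
# 0/1 phenotype over all arrangements preserving class counts and computes
# the exact tail fraction of Q.
oracle_skat_permutation_p <- function(G, y01, weights) {
  n <- length(y01)
  n1 <- sum(y01)
  GW <- sweep(G, 2, weights, "*")
  q_of <- function(y) {
    r <- y - mean(y)
    sum(as.vector(crossprod(GW, r))^2)
  }
  q_obs <- q_of(y01)
  combs <- utils::combn(n, n1)
  qs <- apply(combs, 2, function(ones) {
    y <- numeric(n)
    y[ones] <- 1
    q_of(y)
  })
  mean(qs >= q_obs - 1e-12)
}

# Orthonormal-design fixture: X with (1/n) X'X = I exactly
make_orthonormal_design <- function(n, p, seed = 1) {
  stopifnot(p <= n)
  withr::with_seed(seed, {
    Q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))[, seq_len(p), drop = FALSE]
    sqrt(n) * Q
  })
}
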