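# Sparse l1l2 (elastic-net) regularised least squares on +/-1 labels,
# solved by proximal gradient (iterative soft-thresholding). Label
# regression with sign prediction: the classifier in the l1l2FS lineage.

#' Elastic-net solver configuration
#'
#' @param tau_grid descending vector of positive l1 strengths; `NULL` (the
#'   default) derives a 20-point log-spaced grid in
#'   `[1e-3 * tau_max, tau_max]` from each learning set via
#'   [l1l2_tau_grid()].
#' @param mu nonnegative l2 (ridge) strength.
#' @param max_iter maximum proximal-gradient iterations per fit.
#' @param tol convergence tolerance on the relative objective change.
#' @param fit_intercept whether to fit an unpenalised intercept.
#' @return an `elastic_net_config` list.
#' @export
elastic_net_config <- function(tau_grid = NULL, mu = 1e-2, max_iter = 1000,
                               tol = 1e-6, fit_intercept = TRUE) {
  if (!is.null(tau_grid)) {
    if (!length(tau_grid) || any(tau_grid <= 0)) {
      stop_format("tau_grid must be non-empty and strictly positive")
    }
    tau_grid <- sort(tau_grid, decreasing = TRUE)
  }
  if (mu < 0) stop_format("mu must be >= 0")
  if (tol <= 0) stop_format("tol must be > 0")
  structure(list(tau_grid = tau_grid, mu = mu, max_iter = max_iter,
                 tol = tol, fit_intercept = fit_intercept),
            class = "elastic_net_config")
}

# largest squared singular value by deterministic power iteration
spectral_norm_sq <- function(X) {
  p <- ncol(X)
  if (p == 0) return(0)
  v <- rep(1 / sqrt(p), p)
  ev <- 0
  for (it in 1:200) {
    u <- as.vector(crossprod(X, X %*% v))
    nrm <- sqrt(sum(u^2))
    if (nrm == 0) return(0)
    v_new <- u / nrm
    if (abs(nrm - ev) <= 1e-12 * max(1, ev)) {
      ev <- nrm
      break
    }
    ev <- nrm
    v <- v_new
  }
  ev
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' The smallest l1 strength with an all-zero solution
#'
#' `tau_max = max_j |(2/n) x_j' (y - ybar)|` (with `ybar = 0` when no
#' intercept is fitted). For any `tau >= tau_max` the l1l2 minimiser is
#' exactly the zero vector.
#'
#' @param X numeric matrix (subjects x features).
#' @param y labels in `{+1, -1}` (any numeric response works).
#' @param fit_intercept whether the model has an unpenalised intercept.
#' @return a positive scalar.
#' @export
l1l2_tau_max <- function(X, y, fit_intercept = TRUE) {
  yc <- if (fit_intercept) y - mean(y) else y
  Xc <- if (fit_intercept) sweep(X, 2, colMeans(X)) else X
  max(abs(as.vector(crossprod(Xc, yc))) * 2 / nrow(X))
}

#' Default log-spaced l1 grid
#'
#' @param X,y as in [l1l2_tau_max()].
#' @param n_tau number of grid points.
#' @param min_ratio smallest tau as a fraction of `tau_max`.
#' @param fit_intercept whether the model has an intercept.
#' @return descending numeric vector of length `n_tau`.
#' @export
l1l2_tau_grid <- function(X, y, n_tau = 20, min_ratio = 1e-3,
                          fit_intercept = TRUE) {
  tmax <- l1l2_tau_max(X, y, fit_intercept)
  exp(seq(log(tmax), log(min_ratio * tmax), length.out = n_tau))
}

#' Fit the l1l2-regularised least-squares classifier
#'
#' Minimises
#' `J(w, b) = (1/n) ||y - Xw - b||^2 + mu ||w||_2^2 + tau ||w||_1`
#' by proximal gradient descent with fixed step `1/L`,
#' `L = 2 (sigma_max^2(X)/n + mu)`. The intercept, when fitted, is profiled
#' out exactly by centring `X` and `y`. The objective is non-increasing
#' across iterations; iteration stops when the relative objective decrease
#' falls below `tol` or after `max_iter` iterations (the latter sets
#' `converged = FALSE` and raises a warning, not an error). Prediction is
#' `sign(Xw + b)` (ties to +1).
#'
#' @param X numeric matrix, subjects x features, finite entries.
#' @param y numeric labels in `{+1, -1}` (both classes present).
#' @param tau positive l1 strength.
#' @param mu nonnegative l2 strength.
#' @param max_iter,tol,fit_intercept see [elastic_net_config()].
#' @param w_init optional warm-start weight vector.
#' @param L optional precomputed Lipschitz constant (shared across a path).
#' @return list with `w`, `intercept`, `objective` (per-iteration values),
#'   `converged`, `iterations`, `tau`, `mu`.
#' @export
fit_l1l2 <- function(X, y, tau, mu = 1e-2, max_iter = 1000, tol = 1e-6,
                     fit_intercept = TRUE, w_init = NULL, L = NULL) {
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop_format("non-finite entries in X or y")
  }
  n <- nrow(X)
  if (length(y) != n) stop_format("rows(X) != length(y)")
  if (fit_intercept) {
    xm <- colMeans(X)
    ym <- mean(y)
    Xc <- sweep(X, 2, xm)
    yc <- y - ym
  } else {
    Xc <- X
    yc <- y
  }
  if (is.null(L)) L <- 2 * (spectral_norm_sq(Xc) / n + mu) * (1 + 1e-9)
  w <- if (is.null(w_init)) numeric(ncol(X)) else w_init
  obj <- function(w, resid) {
    mean(resid^2) + mu * sum(w^2) + tau * sum(abs(w))
  }
  # monotone FISTA: accelerated proximal gradient with a descent safeguard
  # (extrapolated step kept only if it lowers the objective) and restart,
  # so the recorded objective is non-increasing by construction
  resid <- yc - as.vector(Xc %*% w)
  J <- obj(w, resid)
  v <- w            # extrapolation point
  t_k <- 1
  objective <- numeric(max_iter)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    resid_v <- yc - as.vector(Xc %*% v)
    grad <- -as.vector(crossprod(Xc, resid_v)) * (2 / n) + 2 * mu * v
    z <- soft_threshold(v - grad / L, tau / L)
    J_z <- obj(z, yc - as.vector(Xc %*% z))
    if (J_z <= J) {
      w_new <- z
      J_new <- J_z
      t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
      v <- w_new + ((t_k - 1) / t_next) * (w_new - w)
      t_k <- t_next
    } else {
      # restart momentum and take a plain proximal step from w
      resid_w <- yc - as.vector(Xc %*% w)
      grad_w <- -as.vector(crossprod(Xc, resid_w)) * (2 / n) + 2 * mu * w
      w_new <- soft_threshold(w - grad_w / L, tau / L)
      J_new <- obj(w_new, yc - as.vector(Xc %*% w_new))
      v <- w_new
      t_k <- 1
    }
    objective[it] <- J_new
    delta <- J - J_new
    w <- w_new
    J <- J_new
    if (delta >= 0 && delta <= tol * max(1, abs(J))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("fit_l1l2: not converged in %d iterations", max_iter),
            call. = FALSE)
  }
  b <- if (fit_intercept) ym - sum(xm * w) else 0
  list(w = w, intercept = b, objective = objective[seq_len(it)],
       converged = converged, iterations = it, tau = tau, mu = mu)
}

#' Fit an l1l2 path over a descending tau grid with warm starts
#'
#' @inheritParams fit_l1l2
#' @param tau_grid descending vector of positive l1 strengths.
#' @return list of [fit_l1l2()] results, one per grid point.
#' @export
fit_l1l2_path <- function(X, y, tau_grid, mu = 1e-2, max_iter = 1000,
                          tol = 1e-6, fit_intercept = TRUE) {
  tau_grid <- sort(tau_grid, decreasing = TRUE)
  Xc <- if (fit_intercept) sweep(X, 2, colMeans(X)) else X
  L <- 2 * (spectral_norm_sq(Xc) / nrow(X) + mu) * (1 + 1e-9)
  fits <- vector("list", length(tau_grid))
  w <- NULL
  for (k in seq_along(tau_grid)) {
    fits[[k]] <- suppressWarnings(
      fit_l1l2(X, y, tau_grid[k], mu = mu, max_iter = max_iter, tol = tol,
               fit_intercept = fit_intercept, w_init = w, L = L))
    w <- fits[[k]]$w
  }
  fits
}

#' Subgradient optimality residual of an l1l2 solution
#'
#' Per-coordinate violation of the Karush-Kuhn-Tucker conditions of the l1l2
#' objective; the maximum over coordinates is 0 at an exact minimiser.
#'
#' @param X,y the data the model was fitted on.
#' @param fit a [fit_l1l2()] result.
#' @return the maximum per-coordinate KKT violation.
#' @export
l1l2_kkt_residual <- function(X, y, fit) {
  n <- nrow(X)
  resid <- y - as.vector(X %*% fit$w) - fit$intercept
  grad <- -as.vector(crossprod(X, resid)) * (2 / n) + 2 * fit$mu * fit$w
  active <- fit$w != 0
  viol <- numeric(length(fit$w))
  viol[active] <- abs(grad[active] + fit$tau * sign(fit$w[active]))
  viol[!active] <- pmax(abs(grad[!active]) - fit$tau, 0)
  max(viol)
}
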