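# Overlapping group lasso over pathway groups: SNPs are mapped through
# their genes into the (possibly overlapping) pathways of a group; overlap
# is realised by the latent-duplication formulation, where a SNP column is
# copied once per pathway containing one of its genes and each copy is
# penalised within its own block.

#' Build the latent-duplication design for one pathway group
#'
#' Every (SNP, pathway) membership pair becomes one expanded column: a copy
#' of the SNP's encoded column assigned to that pathway's block. A SNP
#' belongs to a pathway when any of its region's genes (both flanking genes
#' for an intergenic region) is in the pathway's gene set. Column order is
#' deterministic: pathway order within the group, then encoded SNP order.
#'
#' @param encoded an `encoded_matrix` from [encode_genotypes()].
#' @param annotation a `snp_annotation`.
#' @param groups a `pathway_groups`.
#' @param group_id the group to expand.
#' @return a `group_design`: `list(group_id, pathway_ids, X (expanded
#'   matrix), block (factor over expanded columns), snp_id (per expanded
#'   column), d (block sizes))`.
#' @export
build_group_design <- function(encoded, annotation, groups, group_id) {
  if (!group_id %in% names(groups$groups)) {
    stop_format("unknown group_id %s", group_id)
  }
  pw_ids <- groups$groups[[group_id]]
  genes_of_snp <- region_genes(
    annotation$region_id[match(encoded$snp_ids, annotation$snp_id)])
  cols <- list()
  block <- character(0)
  snp_col <- integer(0)
  for (pw in pw_ids) {
    set <- groups$pathways[[pw]]
    member <- vapply(genes_of_snp, function(g) any(g %in% set), TRUE)
    js <- which(member)
    if (!length(js)) next
    block <- c(block, rep(pw, length(js)))
    snp_col <- c(snp_col, js)
  }
  if (!length(snp_col)) {
    stop_format("group %s: no encoded SNP maps into any of its pathways",
                group_id)
  }
  X <- encoded$X[, snp_col, drop = FALSE]
  colnames(X) <- paste(encoded$snp_ids[snp_col], block, sep = "@")
  block <- factor(block, levels = unique(block))
  structure(list(group_id = group_id, pathway_ids = levels(block), X = X,
                 block = block, snp_id = encoded$snp_ids[snp_col],
                 d = as.integer(table(block))),
            class = "group_design")
}

group_lasso_penalty <- function(v, block_idx, lambda, sqrt_d) {
  norms <- vapply(seq_along(block_idx),
                  function(g) sqrt(sum(v[block_idx[[g]]]^2)), 0)
  lambda * sum(sqrt_d * norms)
}

logistic_loss <- function(eta, y) mean(log1p(exp(-y * eta)))

#' Smallest lambda with an all-zero group-lasso solution
#'
#' With the intercept at its null optimum (log odds of the class balance),
#' the zero vector solves the penalised problem iff
#' `||grad_g loss(0)|| <= lambda * sqrt(d_g)` for every block; the returned
#' value is the smallest such lambda.
#'
#' @param X expanded design matrix.
#' @param y labels in `{+1, -1}`.
#' @param block factor assigning expanded columns to blocks.
#' @return a positive scalar.
#' @export
group_lasso_lambda_max <- function(X, y, block) {
  n <- nrow(X)
  b0 <- log(sum(y == 1) / sum(y == -1))
  p_ <- stats::plogis(-y * b0)
  grad <- as.vector(crossprod(X, -y * p_)) / n
  block_idx <- split(seq_along(grad), block)
  d <- lengths(block_idx)
  max(vapply(seq_along(block_idx),
             function(g) sqrt(sum(grad[block_idx[[g]]]^2)) / sqrt(d[g]), 0))
}

#' Fit the (overlapping) group lasso by proximal gradient
#'
#' Minimises the logistic objective
#' `(1/n) sum_i log(1 + exp(-y_i (x_i' v + b))) +
#'  lambda sum_g sqrt(d_g) ||v_g||_2`
#' by proximal gradient descent with the block soft-thresholding prox
#' `v_g <- v_g max(0, 1 - step lambda sqrt(d_g) / ||v_g||)` and an
#' unpenalised intercept. The step is `1 / L` with
#' `L = sigma_max^2([X 1]) / (4n)`, the logistic curvature bound, so the
#' objective is non-increasing across iterations. Non-convergence within
#' `max_iter` flags the result (partial solution returned, no exception).
#' On a design built by [build_group_design()], the effective weight of a
#' SNP is the sum of its copies' weights across blocks.
#'
#' @param X expanded design matrix (subjects x expanded columns).
#' @param y labels in `{+1, -1}`, both classes present.
#' @param block factor over expanded columns.
#' @param lambda nonnegative penalty strength.
#' @param max_iter,tol solver controls (relative objective change).
#' @param v_init,b_init optional warm start.
#' @param L optional precomputed curvature bound (shared across a path).
#' @return list with `v`, `intercept`, `block_norms` (named), `objective`,
#'   `converged`, `iterations`, `lambda`.
#' @export
fit_overlap_group_lasso <- function(X, y, block, lambda, max_iter = 500,
                                    tol = 1e-7, v_init = NULL, b_init = NULL,
                                    L = NULL) {
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2) {
    stop_format("y must contain both classes, coded +1/-1")
  }
  n <- nrow(X)
  block <- factor(block, levels = unique(as.character(block)))
  block_idx <- split(seq_len(ncol(X)), block)
  sqrt_d <- sqrt(lengths(block_idx))
  if (is.null(L)) {
    L <- (spectral_norm_sq(cbind(X, 1)) / (4 * n)) * (1 + 1e-9)
  }
  step <- 1 / L
  v <- v_init %||% numeric(ncol(X))
  b <- b_init %||% log(sum(y == 1) / sum(y == -1))
  eta <- as.vector(X %*% v) + b
  J <- logistic_loss(eta, y) + group_lasso_penalty(v, block_idx, lambda, sqrt_d)
  objective <- numeric(max_iter)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    p_ <- stats::plogis(-y * eta)
    grad_v <- as.vector(crossprod(X, -y * p_)) / n
    grad_b <- mean(-y * p_)
    v <- v - step * grad_v
    b <- b - step * grad_b
    for (g in seq_along(block_idx)) {
      idx <- block_idx[[g]]
      nrm <- sqrt(sum(v[idx]^2))
      thr <- step * lambda * sqrt_d[g]
      v[idx] <- if (nrm <= thr) 0 else v[idx] * (1 - thr / nrm)
    }
    eta <- as.vector(X %*% v) + b
    J_new <- logistic_loss(eta, y) +
      group_lasso_penalty(v, block_idx, lambda, sqrt_d)
    objective[it] <- J_new
    if (abs(J - J_new) <= tol * max(1, abs(J))) {
      converged <- TRUE
      J <- J_new
      break
    }
    J <- J_new
  }
  block_norms <- vapply(block_idx, function(idx) sqrt(sum(v[idx]^2)), 0)
  list(v = v, intercept = b, block_norms = block_norms,
       objective = objective[seq_len(it)], converged = converged,
       iterations = it, lambda = lambda)
}

#' Fit a group-lasso path over a descending lambda grid with warm starts
#'
#' @inheritParams fit_overlap_group_lasso
#' @param lambda_path descending vector of penalty strengths; `NULL`
#'   derives `n_lambda` log-spaced points in
#'   `[min_ratio * lambda_max, lambda_max]`.
#' @param n_lambda,min_ratio path construction controls.
#' @return list of [fit_overlap_group_lasso()] results.
#' @export
group_lasso_path <- function(X, y, block, lambda_path = NULL, n_lambda = 10,
                             min_ratio = 0.01, max_iter = 500, tol = 1e-7) {
  if (is.null(lambda_path)) {
    lmax <- group_lasso_lambda_max(X, y, block)
    lambda_path <- exp(seq(log(lmax), log(min_ratio * lmax),
                           length.out = n_lambda))
  }
  lambda_path <- sort(lambda_path, decreasing = TRUE)
  L <- (spectral_norm_sq(cbind(X, 1)) / (4 * nrow(X))) * (1 + 1e-9)
  fits <- vector("list", length(lambda_path))
  v <- NULL
  b <- NULL
  for (k in seq_along(lambda_path)) {
    fits[[k]] <- fit_overlap_group_lasso(X, y, block, lambda_path[k],
                                         max_iter = max_iter, tol = tol,
                                         v_init = v, b_init = b, L = L)
    v <- fits[[k]]$v
    b <- fits[[k]]$intercept
  }
  fits
}

#' Select pathways and score one group on held-out data
#'
#' Stratified learning/test split (default 75/25, seeded), lambda chosen on
#' the learning set by inner stratified cross-validation maximising balanced
#' accuracy (ties towards the largest lambda, i.e. the sparsest model),
#' refit on the learning set, then scored on the test split. Selected
#' pathways are the blocks with nonzero norm in the refit.
#'
#' @param design a `group_design` from [build_group_design()].
#' @param labels a `task_labels`; rows of the design are matched to its
#'   subjects.
#' @param lambda_path optional descending lambda path (default derived from
#'   the learning set: `n_lambda` log-spaced points down to
#'   0.01 lambda_max).
#' @param test_fraction held-out fraction.
#' @param inner_folds stratified folds for lambda selection.
#' @param seed integer seed for split and folds.
#' @param n_lambda length of the derived lambda path.
#' @param max_iter,tol solver controls.
#' @return a `pathway_selection`: `list(group_id, selected_pathways,
#'   block_norms, test_score, lambda, converged, n_pathways)`.
#' @export
score_group <- function(design, labels, lambda_path = NULL,
                        test_fraction = 0.25, inner_folds = 3, seed,
                        n_lambda = 10, max_iter = 500, tol = 1e-7) {
  if (missing(seed) || is.null(seed)) stop_format("seed is mandatory")
  idx <- match(labels$subject_ids, rownames(design$X))
  if (anyNA(idx)) stop_format("labels contain subjects absent from design")
  X <- design$X[idx, , drop = FALSE]
  y <- labels$y
  with_seed(seed, {
    test <- stratified_split(y, test_fraction)
    X_learn <- X[!test, , drop = FALSE]
    y_learn <- y[!test]
    if (is.null(lambda_path)) {
      lmax <- group_lasso_lambda_max(X_learn, y_learn, design$block)
      lambda_path <- exp(seq(log(lmax), log(0.01 * lmax),
                             length.out = n_lambda))
    }
    folds <- stratified_folds(y_learn, inner_folds)
    ba <- matrix(NA_real_, inner_folds, length(lambda_path))
    for (f in seq_len(inner_folds)) {
      tr <- folds != f
      fits <- group_lasso_path(X_learn[tr, , drop = FALSE], y_learn[tr],
                               design$block, lambda_path,
                               max_iter = max_iter, tol = tol)
      for (k in seq_along(lambda_path)) {
        pred <- sign_pred(X_learn[!tr, , drop = FALSE] %*% fits[[k]]$v +
                            fits[[k]]$intercept)
        ba[f, k] <- balanced_accuracy(y_learn[!tr], pred)
      }
    }
    best <- which.max(colMeans(ba))  # descending path: first max = largest
    refit <- group_lasso_path(X_learn, y_learn, design$block,
                              lambda_path[seq_len(best)],
                              max_iter = max_iter, tol = tol)[[best]]
    pred <- sign_pred(X[test, , drop = FALSE] %*% refit$v + refit$intercept)
    structure(list(group_id = design$group_id,
                   selected_pathways =
                     names(refit$block_norms)[refit$block_norms > 0],
                   block_norms = refit$block_norms,
                   test_score = balanced_accuracy(y[test], pred),
                   lambda = lambda_path[best],
                   converged = refit$converged,
                   n_pathways = length(design$pathway_ids)),
              class = "pathway_selection")
  })
}

#' Pathway-level scan over all groups
#'
#' Builds the expanded design of every pathway group and scores it with
#' [score_group()]; groups whose design is empty (no encoded SNP maps into
#' any pathway) are skipped with a message.
#'
#' @param encoded an `encoded_matrix`.
#' @param annotation a `snp_annotation`.
#' @param groups a `pathway_groups`.
#' @param labels a `task_labels`.
#' @param seed base seed; group `i` uses `seed + i`.
#' @param ... passed to [score_group()].
#' @return named list of `pathway_selection`, one per scored group.
#' @export
pathway_scan <- function(encoded, annotation, groups, labels, seed, ...) {
  if (missing(seed) || is.null(seed)) stop_format("seed is mandatory")
  out <- list()
  for (i in seq_along(groups$groups)) {
    gid <- names(groups$groups)[i]
    design <- tryCatch(build_group_design(encoded, annotation, groups, gid),
                       error = function(e) NULL)
    if (is.null(design)) {
      message(sprintf("pathway_scan: skipping empty group %s", gid))
      next
    }
    out[[gid]] <- score_group(design, labels, seed = seed + i, ...)
  }
  out
}

#' Tabulate a pathway scan (one row per pathway)
#'
#' @param scan named list of `pathway_selection` from [pathway_scan()].
#' @return data frame with columns `group_id`, `pathway_id`, `selected`,
#'   `block_norm`, `test_score`, `lambda`.
#' @export
pathway_scan_table <- function(scan) {
  do.call(rbind, lapply(scan, function(s) {
    data.frame(group_id = s$group_id,
               pathway_id = names(s$block_norms),
               selected = names(s$block_norms) %in% s$selected_pathways,
               block_norm = unname(s$block_norms),
               test_score = s$test_score,
               lambda = s$lambda,
               row.names = NULL)
  }))
}
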