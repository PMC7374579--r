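# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

#' Stratified train/test split of +/-1 labels
#'
#' Returns logical vector `test` marking the held-out subjects. Sampling is
#' done within each class so class proportions are preserved up to rounding.
#' @noRd
stratified_split <- function(y, test_fraction) {
  test <- logical(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_test <- max(1L, round(length(idx) * test_fraction))
    if (n_test >= length(idx)) {
      stop_format("class %s has too few members (%d) for test fraction %.2f",
                  format(cls), length(idx), test_fraction)
    }
    test[sample(idx, n_test)] <- TRUE
  }
  test
}

#' Stratified fold assignment for inner cross-validation
#' @noRd
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      stop_format("class %s has %d members; cannot build %d stratified folds",
                  format(cls), length(idx), k)
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Sign prediction with deterministic tie-break (0 maps to +1)
#' @noRd
sign_pred <- function(score) {
  ifelse(score >= 0, 1, -1)
}

#' Deterministic TSV writer (UTF-8, tab-separated, no quoting surprises)
#' @noRd
write_tsv_file <- function(df, path) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE, quote = "",
                    comment.char = "", ...)
}
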