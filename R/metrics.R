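# Binary classification metrics on +/-1 labels.

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity:
#' `(TP/(TP+FN) + TN/(TN+FP)) / 2`. Both classes must be present in
#' `y_true`.
#'
#' @param y_true,y_pred vectors of labels in `{+1, -1}`, same length.
#' @return a number in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  check_labels(y_true, y_pred)
  sens <- mean(y_pred[y_true == 1] == 1)
  spec <- mean(y_pred[y_true == -1] == -1)
  if (is.nan(sens) || is.nan(spec)) {
    stop_format("balanced accuracy needs both classes in y_true")
  }
  (sens + spec) / 2
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' whenever any factor of the denominator is 0 (degenerate confusion matrix).
#'
#' @param y_true,y_pred vectors of labels in `{+1, -1}`, same length.
#' @return a number in `[-1, 1]`.
#' @export
mcc <- function(y_true, y_pred) {
  check_labels(y_true, y_pred)
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == -1 & y_pred == -1)
  fp <- sum(y_true == -1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == -1)
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
}

check_labels <- function(y_true, y_pred) {
  if (!length(y_true)) stop_format("empty label vector")
  if (length(y_true) != length(y_pred)) {
    stop_format("y_true and y_pred lengths differ")
  }
  if (!all(c(y_true, y_pred) %in% c(-1, 1))) {
    stop_format("labels must be in {+1, -1}")
  }
  invisible(TRUE)
}
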