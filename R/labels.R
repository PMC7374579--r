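#' Build binary classification labels for one of the two tasks
#'
#' The two supervised tasks mirror the study design on a case/control cohort
#' with APOE genotype:
#' \describe{
#'   \item{`"cases_controls"`}{+1 for diagnosed cases, -1 for controls.}
#'   \item{`"apoe_e4"`}{+1 for carriers of at least one APOE e4 allele
#'     (`apoe_e4_count >= 1`), -1 for non-carriers.}
#' }
#' Subjects with a missing value in the field the task needs are dropped (the
#' count is reported via a message); retained subjects keep their original
#' order. A task with fewer than two subjects in either class is rejected.
#'
#' @param ds a [genotype_dataset()].
#' @param task `"cases_controls"` or `"apoe_e4"`.
#' @return a `task_labels` object: `list(task, subject_ids, y, n_pos, n_neg,
#'   n_dropped)` with `y` in `{+1, -1}` aligned to `subject_ids`.
#' @export
make_task_labels <- function(ds, task = c("cases_controls", "apoe_e4")) {
  task <- match.arg(task)
  ph <- ds$phenotype
  if (task == "cases_controls") {
    field <- ph$diagnosis
    keep <- !is.na(field) & field %in% c("case", "control")
    y <- ifelse(field[keep] == "case", 1, -1)
  } else {
    field <- ph$apoe_e4_count
    keep <- !is.na(field)
    y <- ifelse(field[keep] >= 1, 1, -1)
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("task %s: dropped %d subject(s) with missing phenotype",
                    task, n_dropped))
  }
  n_pos <- sum(y == 1)
  n_neg <- sum(y == -1)
  if (n_pos < 2 || n_neg < 2) {
    stop_format("degenerate task %s: class counts %d/%d (need >= 2 each)",
                task, n_pos, n_neg)
  }
  structure(list(task = task,
                 subject_ids = ds$subject_ids[keep],
                 y = as.numeric(y),
                 n_pos = n_pos, n_neg = n_neg,
                 n_dropped = n_dropped),
            class = "task_labels")
}

#' @export
print.task_labels <- function(x, ...) {
  cat(sprintf("task_labels '%s': %d subjects (+1: %d, -1: %d; dropped %d)\n",
              x$task, length(x$y), x$n_pos, x$n_neg, x$n_dropped))
  invisible(x)
}
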