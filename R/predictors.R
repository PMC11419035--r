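#' Evaluation of amyloidogenicity predictors
#'
#' Scores externally produced predictions against clinical cohort labels.
#' AL-labelled records form the positive (amyloidogenic) class; MM and
#' polyclonal control records the negative class. Records for which a tool
#' returned no prediction are excluded from the confusion table and counted.
#'
#' @name predictor_evaluation
#' @keywords internal
NULL

#' Build a confusion table from a prediction table
#'
#' @param predictions data.frame with `record_id` and `call` in
#'   `{"amyloidogenic", "non-amyloidogenic", NA}` (missing = no prediction
#'   returned).
#' @param labels data.frame with `record_id` and `cohort`; `positive_cohorts`
#'   members are the positive class, everything else negative.
#' @param positive_cohorts cohort labels defining the positive class.
#' @return `ConfusionCounts`: list with `tp`, `fp`, `tn`, `fn`, `n_missing`.
#' @export
build_confusion <- function(predictions, labels,
                            positive_cohorts = c("AL", "AL/MM")) {
  idx <- match(predictions$record_id, labels$record_id)
  if (anyNA(idx))
    stop_lcrep("prediction id(s) without label: ",
               paste(predictions$record_id[is.na(idx)], collapse = ", "))
  call <- predictions$call
  missing <- is.na(call) | call == "missing"
  if (all(missing))
    warning("all predictions missing: empty confusion table")
  truth_pos <- labels$cohort[idx] %in% positive_cohorts
  pred_pos <- !missing & call == "amyloidogenic"
  keep <- !missing
  structure(list(
    tp = sum(keep & truth_pos & pred_pos),
    fp = sum(keep & !truth_pos & pred_pos),
    tn = sum(keep & !truth_pos & !pred_pos),
    fn = sum(keep & truth_pos & !pred_pos),
    n_missing = sum(missing)), class = "ConfusionCounts")
}

#' Sensitivity, specificity and accuracy of a confusion table
#'
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`,
#' `accuracy = (tp+tn)/(tp+tn+fp+fn)`. A metric with a zero denominator is
#' reported as `NA` (not available), never as 0.
#'
#' @param confusion a `ConfusionCounts` (or any list with tp/fp/tn/fn).
#' @return list with `sensitivity`, `specificity`, `accuracy`.
#' @examples
#' metrics(list(tp = 120, fn = 35, tn = 1300, fp = 135))$accuracy  # 0.8931...
#' @export
metrics <- function(confusion) {
  tp <- confusion$tp; fp <- confusion$fp
  tn <- confusion$tn; fn <- confusion$fn
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = div(tp, tp + fn),
       specificity = div(tn, tn + fp),
       accuracy = div(tp + tn, tp + tn + fp + fn))
}

#' Evaluate a multi-tool prediction table
#'
#' @param predictions data.frame with `record_id`, `tool`, `call`, and
#'   optionally `chain` capability filtering via `tool_chains` (e.g. a
#'   lambda-only tool is scored on lambda records only).
#' @param labels data.frame with `record_id`, `cohort`, optionally `locus`.
#' @param tool_chains optional named list mapping tool to accepted loci
#'   (e.g. `list(LICTOR = "IGL")`).
#' @param positive_cohorts see [build_confusion()].
#' @return data.frame with one row per tool: confusion counts, number of
#'   missing predictions, and the three metrics.
#' @export
evaluate_predictions <- function(predictions, labels, tool_chains = NULL,
                                 positive_cohorts = c("AL", "AL/MM")) {
  stopifnot(all(c("record_id", "tool", "call") %in% names(predictions)))
  rows <- list()
  for (tool in unique(predictions$tool)) {
    p <- predictions[predictions$tool == tool, , drop = FALSE]
    if (!is.null(tool_chains) && tool %in% names(tool_chains)) {
      if (!"locus" %in% names(labels))
        stop_lcrep("tool_chains given but labels carry no locus column")
      ok <- labels$record_id[labels$locus %in% tool_chains[[tool]]]
      p <- p[p$record_id %in% ok, , drop = FALSE]
    }
    cm <- build_confusion(p, labels, positive_cohorts)
    m <- metrics(cm)
    rows[[tool]] <- data.frame(
      tool = tool, tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
      n_missing = cm$n_missing, n_evaluated = cm$tp + cm$fp + cm$tn + cm$fn,
      sensitivity = m$sensitivity, specificity = m$specificity,
      accuracy = m$accuracy, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}
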