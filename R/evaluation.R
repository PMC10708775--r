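#' @title Evaluation metrics against simulator ground truth
#' @description The five run-level metrics: false rate, spurious fluctuation
#'   rate, data-analysis rate, recommendation ratio and consistency check,
#'   each a proportion in `[0, 1]` computed against the synthetic crowd's
#'   ground-truth labels and event log.
#' @name evaluation
NULL

#' False rate of person-level infection judgements
#'
#' Misinterpretations (non-infected judged infected plus infected judged
#' non-infected) over all judged persons.
#'
#' @param decided Logical vector: judged infected.
#' @param truth Logical vector: ground-truth infected.
#' @return Proportion in `[0, 1]`.
#' @export
compute_false_rate <- function(decided, truth) {
  if (!length(decided)) stop("empty decision stream")
  stopifnot(length(decided) == length(truth))
  mean(decided != truth)
}

#' Balanced accuracy of person-level infection judgements
#'
#' Mean of sensitivity and specificity; `NA` when either class is absent.
#'
#' @inheritParams compute_false_rate
#' @return Proportion in `[0, 1]` or `NA`.
#' @export
balanced_accuracy <- function(decided, truth) {
  if (!any(truth) || !any(!truth)) return(NA_real_)
  (mean(decided[truth]) + mean(!decided[!truth])) / 2
}

#' Spurious fluctuation rate
#'
#' Fraction of intervals flagged as fluctuation that contain no injected
#' artifact event; 0 when nothing is flagged.
#'
#' @param classified Data frame with `person_id`, `label`, `step_start`,
#'   `step_end`.
#' @param events Ground-truth event log.
#' @return Proportion in `[0, 1]`.
#' @export
compute_fluctuation_rate <- function(classified, events) {
  fl <- classified[classified$label == "fluctuation", , drop = FALSE]
  if (!nrow(fl)) return(0)
  spurious <- vapply(seq_len(nrow(fl)), function(i) {
    !any(events$person_id == fl$person_id[i] &
           events$kind == "artifact" &
           events$start <= fl$step_end[i] &
           events$end >= fl$step_start[i])
  }, logical(1))
  mean(spurious)
}

#' Data-analysis rate
#'
#' Fraction of sensed readings that end up inside a fully assessed interval
#' of an operating device: dropped readings, readings in discarded partial
#' windows, and readings of discharged (`omega = 0`) devices do not count.
#'
#' @param assessment Combined interval table (all persons), with
#'   `n_readings`.
#' @param omega Named integer vector of device-operating flags per
#'   `person_id`.
#' @param total_readings Total readings sensed (before dropouts).
#' @return Proportion in `[0, 1]`.
#' @export
compute_data_analysis_rate <- function(assessment, omega, total_readings) {
  if (total_readings == 0) return(0)
  op <- omega[assessment$person_id] == 1
  sum(assessment$n_readings[op]) / total_readings
}

#' Recommendation ratio
#'
#' Fraction of ground-truth abnormal episodes (injected artifact/saturation
#' events belonging to infected persons) that received at least one health
#' recommendation in an interval overlapping the episode's step span. `NA`
#' when there are no such episodes.
#'
#' @param alerts Alert data frame from [issue_recommendations()].
#' @param events Ground-truth event log.
#' @param infected Named logical vector of ground-truth infection per
#'   `person_id`.
#' @param assessment Combined interval table mapping `interval_index` to step
#'   spans per person.
#' @return Proportion in `[0, 1]`, or `NA` with zero episodes.
#' @export
compute_recommendation_ratio <- function(alerts, events, infected, assessment) {
  ep <- events[events$kind != "dropout" &
                 infected[events$person_id], , drop = FALSE]
  if (!nrow(ep)) return(NA_real_)
  health <- alerts[alerts$kind == "abnormal_health", , drop = FALSE]
  hit <- vapply(seq_len(nrow(ep)), function(i) {
    ha <- health[health$person_id == ep$person_id[i], , drop = FALSE]
    if (!nrow(ha)) return(FALSE)
    iv <- assessment[assessment$person_id == ep$person_id[i] &
                       assessment$interval_index %in% ha$interval_index, ,
                     drop = FALSE]
    any(iv$step_start <= ep$end[i] & iv$step_end >= ep$start[i])
  }, logical(1))
  mean(hit)
}

#' Consistency-check success rate
#'
#' Fraction of persons whose [consistency_check_procedure()] reached
#' `sigma_O <= Y/X` before the iteration cap.
#'
#' @param cc_results List of procedure results (one per person).
#' @return Proportion in `[0, 1]`.
#' @export
compute_consistency_check <- function(cc_results) {
  if (!length(cc_results)) return(0)
  mean(vapply(cc_results, `[[`, logical(1), "converged"))
}
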