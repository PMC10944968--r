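#' Classify a trial from its three report responsibilities
#'
#' A trial is `high_accuracy` when the target responsibility exceeds 0.9 in
#' all three reports; otherwise `swap` when the pooled non-target
#' responsibility exceeds 0.7 in at least one report; otherwise
#' `low_accuracy`. The two gates cannot both fire within a report
#' (0.9 + 0.7 > 1) and the all-report rule makes the partition exclusive; the
#' order of the tests is fixed for determinism.
#'
#' @param resp data frame with one row per report (exactly 3) and columns
#'   `p_target`, `p_guess`, `p_nontarget`.
#' @param p_target_threshold,p_nontarget_threshold classification thresholds.
#' @return one of `"high_accuracy"`, `"swap"`, `"low_accuracy"`.
#' @export
classify_trial <- function(resp, p_target_threshold = 0.9,
                           p_nontarget_threshold = 0.7) {
  if (nrow(resp) != 3) stop("classify_trial expects exactly 3 reports")
  if (all(resp$p_target > p_target_threshold)) return("high_accuracy")
  if (any(resp$p_nontarget > p_nontarget_threshold)) return("swap")
  "low_accuracy"
}

#' Classify every trial in a reports table
#'
#' @param reports data frame with columns `trial`, `target`, `reported`,
#'   `nontarget*`.
#' @param params fitted [mixture_params()] for this subject.
#' @inheritParams classify_trial
#' @return data frame with one row per trial: `trial`, `label`.
#' @export
classify_trials <- function(reports, params, p_target_threshold = 0.9,
                            p_nontarget_threshold = 0.7) {
  resp <- responsibilities(reports, params)
  resp$trial <- reports$trial
  labels <- vapply(split(resp, resp$trial), function(d) {
    classify_trial(d, p_target_threshold, p_nontarget_threshold)
  }, character(1))
  out <- data.frame(trial = as.integer(names(labels)), label = unname(labels))
  out[order(out$trial), , drop = FALSE]
}

#' Summarize behavioral performance by trial label
#'
#' Mean absolute circular report error, in degrees, within each trial label,
#' plus label proportions. Labels with no trials are reported with `NA` error
#' and proportion 0.
#'
#' @param reports reports table (`trial`, `target`, `reported`).
#' @param labels data frame from [classify_trials()].
#' @return data frame with columns `label`, `n_trials`, `proportion`,
#'   `mean_abs_error_deg`.
#' @export
behavior_summary <- function(reports, labels) {
  stopifnot(all(reports$trial %in% labels$trial))
  lab <- labels$label[match(reports$trial, labels$trial)]
  abs_err <- abs(rad2deg(circ_diff(reports$reported, reports$target)))
  all_labels <- c("high_accuracy", "low_accuracy", "swap")
  n_tr <- vapply(all_labels,
                 function(l) length(unique(reports$trial[lab == l])),
                 numeric(1))
  me <- vapply(all_labels, function(l) {
    if (any(lab == l)) mean(abs_err[lab == l]) else NA_real_
  }, numeric(1))
  data.frame(label = all_labels, n_trials = n_tr,
             proportion = n_tr / length(unique(reports$trial)),
             mean_abs_error_deg = me, row.names = NULL)
}
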