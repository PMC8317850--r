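# Packaged study fixtures: the published test-data confusion matrix, the
# per-patient frame counts, and the published result values that
# run_paper_tables() re-derives and checks against.

#' Packaged test-data confusion matrix
#'
#' Frame counts of the classifier test data (in/out-of-focus decisions
#' against the annotation, no-detection frames excluded).
#'
#' @return A [confusion_matrix()].
#' @export
confusion_fixture <- function() {
  path <- system.file("extdata", "confusion_test_data.csv",
                      package = "lithogate", mustWork = TRUE)
  d <- utils::read.csv(path)
  confusion_matrix(tp = d$tp, fp = d$fp, fn = d$fn, tn = d$tn)
}

#' Packaged per-patient frame counts
#'
#' One row per treated patient with the number of frames annotated in
#' focus and the total annotated frames. Patients whose stones were not
#' visible on ultrasound carry `included = FALSE` and `NA` counts; the
#' analyzable cohort is the 8 included rows.
#'
#' @param included_only Drop the non-analyzable patients (default TRUE).
#' @return A data.frame with columns `patient_id`, `n_focus`, `n_total`,
#'   `included`.
#' @export
patient_frames_fixture <- function(included_only = TRUE) {
  path <- system.file("extdata", "patient_frames.csv",
                      package = "lithogate", mustWork = TRUE)
  d <- utils::read.csv(path)
  d$patient_id <- as.character(d$patient_id)
  if (included_only) d <- d[d$included, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Published result values used as the verification reference
#'
#' @return A data.frame with columns `quantity`, `value`, `tolerance`,
#'   `kind` (`deterministic` or `stochastic`).
#' @export
reported_results_fixture <- function() {
  path <- system.file("extdata", "reported_results.csv",
                      package = "lithogate", mustWork = TRUE)
  utils::read.csv(path)
}
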