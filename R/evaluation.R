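#' Confusion matrix of firing decisions against annotation
#'
#' Cross-tabulates the algorithm's binary in-focus decisions against the
#' annotator's ground-truth labels. "Positive" is the in-focus class: `tp`
#' counts frames called in focus by both, `fp` frames called in focus by
#' the algorithm but annotated out of focus, and so on.
#'
#' @param decisions,truth Integer 0/1 vectors of equal length (after any
#'   no-detection policy has been applied).
#' @return An object of class `confusion_matrix` with fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(decisions, truth) {
  if (length(decisions) != length(truth))
    stop("decisions and truth must have equal length")
  decisions <- as.integer(decisions); truth <- as.integer(truth)
  confusion_matrix(tp = sum(decisions == 1L & truth == 1L),
                   fp = sum(decisions == 1L & truth == 0L),
                   fn = sum(decisions == 0L & truth == 1L),
                   tn = sum(decisions == 0L & truth == 0L))
}

#' @rdname confusion
#' @param tp,fp,fn,tn Non-negative frame counts.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("confusion matrix must have a positive total")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
              dimnames = list(c("In focus (AI)", "Out of focus (AI)"),
                              c("In focus (annot)", "Out of focus (annot)")))
  print(stats::addmargins(as.table(m)))
  invisible(x)
}

#' Classifier performance metrics
#'
#' Computes the standard binary-classifier panel from a confusion matrix:
#' accuracy, sensitivity, specificity, PPV, NPV, prevalence, detection
#' rate, detection prevalence, balanced accuracy, Youden's J statistic, the
#' no-information rate, and Cohen's kappa
#' (`(p_o - p_e) / (1 - p_e)` with the expected agreement `p_e` taken from
#' the marginals). When the lithotripter fires only on in-focus decisions,
#' the PPV equals the achieved hit rate. Metrics with a zero denominator
#' are reported as `NA`. All values are kept at full precision; rounding
#' happens only in the print method (one decimal in percent, four decimals
#' for kappa).
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `metric_report` (a named list of fractions).
#' @export
classifier_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- frac(tp, tp + fn)
  spec <- frac(tn, tn + fp)
  prev <- (tp + fn) / total
  po <- (tp + tn) / total
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
  structure(list(
    accuracy = po,
    sensitivity = sens,
    specificity = spec,
    ppv = frac(tp, tp + fp),
    npv = frac(tn, tn + fn),
    prevalence = prev,
    detection_rate = tp / total,
    detection_prevalence = (tp + fp) / total,
    balanced_accuracy = (sens + spec) / 2,
    youden_j = sens + spec - 1,
    no_information_rate = max(prev, 1 - prev),
    kappa = if (pe < 1) (po - pe) / (1 - pe) else NA_real_,
    total = total
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  nm <- c(accuracy = "Accuracy", sensitivity = "Sensitivity",
          specificity = "Specificity", ppv = "Positive predictive value",
          npv = "Negative predictive value", prevalence = "Prevalence",
          detection_rate = "Detection rate",
          detection_prevalence = "Detection prevalence",
          balanced_accuracy = "Balanced accuracy",
          youden_j = "Youden's J statistic",
          no_information_rate = "No-information rate")
  cat(sprintf("Classifier performance (%d frames)\n", x$total))
  for (k in names(nm)) cat(sprintf("  %-28s %s\n", nm[k], pct(x[[k]])))
  cat(sprintf("  %-28s %.4f\n", "Cohen's kappa", x$kappa))
  invisible(x)
}

#' Treatment-efficiency estimates
#'
#' Compares gated (algorithm-controlled) firing against continuous
#' operator-controlled firing at a constant pulse rate.
#' `relative_treatment_time` is the factor by which treatment lengthens
#' when firing only on algorithm-positive frames while demanding the same
#' number of true hits: frames annotated in focus divided by true
#' positives. `mishit_ratio` is the gated mishit count over the same
#' treatment horizon relative to operator mishits:
#' `relative_treatment_time * fp / n_out_annot` -- mishits are shots fired
#' while the stone is out of focus, i.e. false positives, scaled by the
#' lengthened treatment. (A methods-text variant phrases this with true
#' negatives; the arithmetic that the reported numbers follow uses the
#' false-positive count, and so does this function -- see the `note`
#' field.) Hits per minute divide the pulse rate between hit and mishit
#' frames by the annotated frame proportions.
#'
#' @param cm A [confusion_matrix()] under the exclude policy.
#' @param n_focus_annot Total frames annotated in focus (all frames, not
#'   only those the algorithm detected).
#' @param n_out_annot Total frames annotated out of focus.
#' @param pulse_rate Shockwaves per minute (default 90).
#' @return An object of class `efficiency_report`.
#' @export
treatment_efficiency <- function(cm, n_focus_annot, n_out_annot,
                                 pulse_rate = 90) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (n_out_annot <= 0) stop("n_out_annot must be positive")
  if (cm$tp == 0) {
    rtt <- NA_real_; mr <- NA_real_
    warning("tp = 0: relative treatment time undefined")
  } else {
    rtt <- n_focus_annot / cm$tp
    mr <- rtt * cm$fp / n_out_annot
  }
  total <- n_focus_annot + n_out_annot
  structure(list(
    relative_treatment_time = rtt,
    mishit_ratio = mr,
    mishit_reduction = 1 - mr,
    hits_per_minute_operator = pulse_rate * n_focus_annot / total,
    hits_per_minute_ai = pulse_rate * cm$tp / total,
    pulse_rate = pulse_rate,
    note = paste("mishit_ratio uses the false-positive count (shots fired",
                 "while the stone is out of focus), not the true-negative",
                 "count")
  ), class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("Relative treatment time  %.2f\n", x$relative_treatment_time))
  cat(sprintf("Mishit ratio             %.1f%% (reduction %.1f%%)\n",
              100 * x$mishit_ratio, 100 * x$mishit_reduction))
  cat(sprintf("Hits/min operator        %.0f\n", x$hits_per_minute_operator))
  cat(sprintf("Hits/min gated           %.0f  (pulse rate %.0f/min)\n",
              x$hits_per_minute_ai, x$pulse_rate))
  invisible(x)
}

#' Metrics under the alternative no-detection policy
#'
#' Relabels every `no_detection` call as out of focus (the stone would not
#' be shot at) and recomputes the full metric panel over all frames,
#' instead of excluding undetected frames. Sensitivity can only decrease
#' relative to the exclude policy, since annotated-in-focus frames among
#' the undetected ones become false negatives.
#'
#' @param calls Character vector of call values (must contain
#'   `no_detection` semantics, see [apply_no_detection_policy()]).
#' @param truth Integer 0/1 annotation for every frame.
#' @return A `metric_report` over all frames.
#' @export
alternative_policy_report <- function(calls, truth) {
  pol <- apply_no_detection_policy(calls, "as_out_of_focus")
  if (length(pol$decisions) != length(truth))
    stop("calls and truth must have equal length")
  classifier_metrics(confusion(pol$decisions, truth))
}
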