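#' Fraction of the stone inside the focal zone
#'
#' Exact pixel counting: the number of predicted-stone pixels inside the
#' focal zone divided by the total number of predicted-stone pixels. All
#' disconnected components of the mask are treated as one stone.
#'
#' @param stone_mask 0/1 matrix (nonempty).
#' @param zone A [focal_zone()].
#' @return Overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(stone_mask, zone) {
  npix <- sum(stone_mask)
  if (npix == 0L) stop("empty stone mask; handle as no_detection upstream")
  fz <- zone_mask(zone, nrow(stone_mask), ncol(stone_mask))
  sum(stone_mask * fz) / npix
}

#' Firing decision for one frame
#'
#' Applies the overlap rule: the frame is "in focus" (fire) when at least
#' `threshold` of the predicted stone lies within the focal zone -- the
#' boundary case counts as in focus (`>=`, not `>`). Masks below
#' `min_pixels` (speckle-level detections) signal `no_detection` instead of
#' a decision; how those frames enter the analysis is a separate policy
#' choice ([apply_no_detection_policy()]).
#'
#' @param stone_mask 0/1 matrix, possibly empty.
#' @param zone A [focal_zone()].
#' @param threshold Overlap threshold in `(0, 1]`; default 0.5.
#' @param min_pixels Minimum mask size counting as a detection; default 5.
#' @return A list of class `focus_call`: `value` one of `"in_focus"`,
#'   `"out_of_focus"`, `"no_detection"`; `overlap` fraction or `NA`.
#' @export
classify_frame <- function(stone_mask, zone, threshold = 0.5,
                           min_pixels = 5L) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (sum(stone_mask) < min_pixels)
    return(structure(list(value = "no_detection", overlap = NA_real_),
                     class = "focus_call"))
  ov <- overlap_fraction(stone_mask, zone)
  structure(list(value = if (ov >= threshold) "in_focus" else "out_of_focus",
                 overlap = ov),
            class = "focus_call")
}

#' Resolve no-detection frames into binary decisions
#'
#' Two policies for frames where no stone was detected: `"exclude"` drops
#' them from the analysis (they are counted, not silently lost), matching
#' the primary analysis; `"as_out_of_focus"` relabels them 0 on the
#' rationale that an undetected stone will not be shot at.
#'
#' @param calls Character vector (or list of `focus_call`s) with values in
#'   `in_focus`, `out_of_focus`, `no_detection`.
#' @param policy `"exclude"` or `"as_out_of_focus"`.
#' @return A list: `decisions` (integer 0/1), `kept` (indices of retained
#'   frames in the input), `n_excluded`.
#' @export
apply_no_detection_policy <- function(calls,
                                      policy = c("exclude", "as_out_of_focus")) {
  policy <- match.arg(policy)
  if (is.list(calls))
    calls <- vapply(calls, function(x) x$value, character(1))
  if (length(calls) == 0L) stop("calls must be nonempty")
  if (!all(calls %in% c("in_focus", "out_of_focus", "no_detection")))
    stop("unknown call value")
  nd <- calls == "no_detection"
  if (policy == "exclude") {
    kept <- which(!nd)
    list(decisions = as.integer(calls[kept] == "in_focus"),
         kept = kept, n_excluded = sum(nd))
  } else {
    list(decisions = as.integer(calls == "in_focus"),
         kept = seq_along(calls), n_excluded = 0L)
  }
}

#' Write firing decisions in the per-frame label dialect
#'
#' Adds a `call` column to the expanded label CSV: 1 = in focus, 0 = out of
#' focus, `NA` = no detection.
#'
#' @param calls Character vector of call values as in
#'   [apply_no_detection_policy()].
#' @param patient_id Patient identifier.
#' @param path Output CSV path.
#' @export
write_decisions <- function(calls, patient_id, path) {
  if (is.list(calls))
    calls <- vapply(calls, function(x) x$value, character(1))
  df <- data.frame(patient_id = patient_id,
                   frame_index = seq_along(calls) - 1L,
                   call = ifelse(calls == "no_detection", NA_integer_,
                                 as.integer(calls == "in_focus")))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
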