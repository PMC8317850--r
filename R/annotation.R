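#' Expand transition-point interval labels to per-frame labels
#'
#' The annotation scheme marks only the transition points between intervals
#' of frames: each record gives the 0-based frame at which a new label
#' starts. Every frame then carries the label of the latest interval that
#' started at or before it, and the last interval extends to the end of the
#' sequence. (The tool-facing narration of "first frame ... tenth frame" is
#' 1-based; indices here are 0-based, so a transition narrated at the tenth
#' frame is `start_frame = 9`.)
#'
#' @param intervals A data.frame with columns `start_frame` (0-based,
#'   strictly increasing, first must be 0) and `label` (0 = out of focus,
#'   1 = in focus).
#' @param n_frames Total number of frames to produce.
#' @return Integer vector of 0/1 labels, length `n_frames`.
#' @export
expand_intervals <- function(intervals, n_frames) {
  if (!all(c("start_frame", "label") %in% names(intervals)))
    stop("intervals needs columns start_frame and label")
  s <- as.integer(intervals$start_frame)
  lab <- as.integer(intervals$label)
  if (length(s) == 0L) stop("no intervals given")
  if (is.unsorted(s, strictly = TRUE))
    stop("start_frame must be strictly increasing (no duplicates)")
  if (s[1L] != 0L) stop("the first interval must start at frame 0")
  if (s[length(s)] >= n_frames)
    stop("last start_frame must be < n_frames")
  if (!all(lab %in% c(0L, 1L))) stop("labels must be 0 or 1")
  spans <- diff(c(s, n_frames))
  rep(lab, spans)
}

#' Compress per-frame labels to transition-point intervals
#'
#' Inverse of [expand_intervals()]: run-length encodes the label vector into
#' one record per maximal constant interval.
#'
#' @param labels Integer 0/1 vector.
#' @return A data.frame with columns `start_frame`, `label` such that
#'   `expand_intervals(compress_labels(x), length(x))` reproduces `x`.
#' @export
compress_labels <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("labels must be nonempty")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  r <- rle(labels)
  data.frame(start_frame = cumsum(c(0L, r$lengths[-length(r$lengths)])),
             label = r$values)
}

#' Sample the start of an annotation window
#'
#' Treatment videos are longer than what gets annotated; a fixed-length
#' window is drawn uniformly from the feasible starts.
#'
#' @param total_frames Length of the full video in frames.
#' @param window_frames Length of the annotation window in frames.
#' @param seed Integer seed.
#' @return A single 0-based start index, uniform on
#'   `0 .. total_frames - window_frames`.
#' @export
sample_window <- function(total_frames, window_frames, seed = 1L) {
  if (window_frames > total_frames)
    stop("window_frames must not exceed total_frames")
  withr::with_seed(as.integer(seed),
                   sample.int(total_frames - window_frames + 1L, 1L) - 1L)
}

#' Flip labels at a given mismatch rate
#'
#' Emulates interobserver variability: each frame label is independently
#' flipped with probability `mismatch_rate`, so the expected fraction of
#' disagreeing frames between the original and returned vectors equals the
#' rate.
#'
#' @param labels Integer 0/1 vector.
#' @param mismatch_rate Flip probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Integer 0/1 vector of the same length.
#' @export
corrupt_labels <- function(labels, mismatch_rate, seed = 1L) {
  if (mismatch_rate < 0 || mismatch_rate > 1)
    stop("mismatch_rate must be in [0, 1]")
  labels <- as.integer(labels)
  flip <- withr::with_seed(as.integer(seed),
    stats::rbinom(length(labels), 1L, mismatch_rate))
  as.integer(xor(labels, flip))
}

#' Read/write per-frame label files
#'
#' The expanded label dialect has one row per frame with columns
#' `patient_id`, `frame_index` (0-based) and `label` (0/1); the interval
#' dialect has columns `patient_id`, `start_frame`, `label`. Both are
#' plain UTF-8 CSV with a header row.
#'
#' @param labels Integer 0/1 vector.
#' @param patient_id Patient identifier string.
#' @param path File path.
#' @return `read_frame_labels` returns the data.frame; writers return the
#'   path invisibly.
#' @export
write_frame_labels <- function(labels, patient_id, path) {
  df <- data.frame(patient_id = patient_id,
                   frame_index = seq_along(labels) - 1L,
                   label = as.integer(labels))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_labels
#' @export
read_frame_labels <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("patient_id", "frame_index", "label") %in% names(df)))
  df
}

#' @rdname write_frame_labels
#' @param intervals Interval data.frame as in [expand_intervals()].
#' @export
write_intervals <- function(intervals, patient_id, path) {
  df <- cbind(patient_id = patient_id, intervals)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_labels
#' @export
read_intervals <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("start_frame", "label") %in% names(df)))
  df
}
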