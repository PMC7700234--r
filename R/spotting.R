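# Gesture spotting: five-class recognition of Fetch / Lift / Sip / Drop /
# Release inside a drinking segment, and extraction of sip intervals.

#' Spot drinking gestures inside a segment
#'
#' Slides short windows (default 16 samples, 50% overlap) over the frames
#' of one drinking segment, extracts the 88 window features, classifies
#' each window with the supplied five-class gesture classifier, and applies
#' the same fragment-revision post-processing as drinking detection: runs
#' of one or two windows inconsistent with identical neighbours are
#' rewritten to the previous run's label.
#'
#' @param frames Frame table of the drinking segment (typically cut from
#'   the smoothed recording); at least one window long.
#' @param spec A `window_spec` (default 16 samples, 50% overlap).
#' @param classifier An `intake_classifier` trained on gesture windows.
#' @param sampling_rate Samples per second.
#' @return Data frame of class `gesture_sequence` with columns `start`
#'   (0-based within the segment) and `label`; attributes `spec` and
#'   `sampling_rate`.
#' @export
spot_gestures <- function(frames, spec = window_spec(16L, 0.5), classifier,
                          sampling_rate = DEFAULT_SAMPLING_RATE) {
  frames <- as.data.frame(frames)
  if (nrow(frames) < spec$window_size) {
    stop("drinking segment shorter than one spotting window", call. = FALSE)
  }
  segs <- segment(nrow(frames), spec)
  feats <- extract_features_matrix(frames, segs$start, spec$window_size)
  lab <- predict(classifier, feats)
  lab <- fragment_revision(lab)
  structure(data.frame(start = segs$start, label = as.character(lab),
                       stringsAsFactors = FALSE),
            class = c("gesture_sequence", "data.frame"),
            spec = spec, sampling_rate = sampling_rate)
}

#' Extract sip intervals from a gesture label sequence
#'
#' Each maximal run of `Sip` windows becomes one sip interval covering the
#' samples `[first * step, last * step + window_size)` of the segment, with
#' duration `((n - 1) * step + window_size) / sampling_rate` seconds. Sips
#' are returned in temporal order and never overlap.
#'
#' @param labels Per-window gesture labels (or a `gesture_sequence`, whose
#'   spec and sampling rate are then used).
#' @param spec A `window_spec` (ignored when `labels` is a
#'   `gesture_sequence`).
#' @param sampling_rate Samples per second.
#' @param offset Sample offset added to the interval bounds, e.g. the start
#'   of the drinking segment in its recording.
#' @return Data frame with columns `start`, `end` (0-based, half-open) and
#'   `duration_s`; zero rows when no window is labelled `Sip`.
#' @export
extract_sips <- function(labels, spec = window_spec(16L, 0.5),
                         sampling_rate = DEFAULT_SAMPLING_RATE,
                         offset = 0L) {
  if (inherits(labels, "gesture_sequence")) {
    spec <- attr(labels, "spec")
    sampling_rate <- attr(labels, "sampling_rate")
    labels <- labels$label
  }
  ev <- extract_events(labels, spec, sampling_rate, class_label = "Sip")
  data.frame(start = ev$start_sample + offset,
             end = ev$end_sample + offset,
             duration_s = ev$duration_s)
}
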