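# Rule-based label post-processing: fragment revision, the minimum-duration
# threshold, and run-length event extraction.

#' Fragment revision
#'
#' Rule-based correction of isolated misclassified window runs: whenever a
#' maximal run of one or two consecutive windows carries a label different
#' from both its neighbours and the two neighbouring runs agree with each
#' other, the run is rewritten to the previous run's label. The scan is a
#' single left-to-right pass over the *original* run structure, so an edit
#' never re-triggers on its own output; the first and last runs, which lack
#' a neighbour on one side, are never altered. Works for any label
#' alphabet (binary detection or five-class gesture spotting).
#'
#' @param labels Character vector or factor of per-window labels.
#' @return Labels of the same type with revised fragments.
#' @export
fragment_revision <- function(labels) {
  was_factor <- is.factor(labels)
  lv <- if (was_factor) levels(labels) else NULL
  lab <- as.character(labels)
  if (length(lab) < 3L) return(labels)
  r <- rle(lab)
  k <- length(r$values)
  if (k >= 3L) {
    vals <- r$values
    new_vals <- vals
    for (j in 2L:(k - 1L)) {
      if (r$lengths[j] <= 2L && vals[j - 1L] == vals[j + 1L] &&
          vals[j] != vals[j - 1L]) {
        new_vals[j] <- vals[j - 1L]
      }
    }
    lab <- inverse.rle(list(values = new_vals, lengths = r$lengths))
  }
  if (was_factor) factor(lab, levels = lv) else lab
}

# Duration in seconds of a run of n consecutive overlapping windows:
# the run spans (n - 1) * step + window_size samples.
run_duration_s <- function(n_windows, spec, sampling_rate) {
  ((n_windows - 1) * spec$step + spec$window_size) / sampling_rate
}

#' Minimum-duration threshold for detected drinking
#'
#' Deletes detected drinking events that are too short to be a complete
#' fluid-intake activity: every maximal run of `drinking` windows whose
#' span `((n - 1) * step + window_size) / sampling_rate` is strictly less
#' than `min_duration_s` is relabelled to `other`. Runs of exactly the
#' threshold duration are kept. Intended to follow [fragment_revision()]
#' in the detection pipeline; the operation is idempotent.
#'
#' @param labels Per-window labels (character or factor).
#' @param spec The `window_spec` the labels were produced under.
#' @param sampling_rate Samples per second.
#' @param min_duration_s Minimum event duration in seconds (default 2).
#' @param drinking,other The positive-class and replacement labels.
#' @return Labels of the same type with sub-threshold events removed.
#' @export
duration_threshold <- function(labels, spec, sampling_rate,
                               min_duration_s = 2,
                               drinking = DRINKING_LABEL,
                               other = OTHER_LABEL) {
  was_factor <- is.factor(labels)
  lv <- if (was_factor) levels(labels) else NULL
  lab <- as.character(labels)
  if (!length(lab)) return(labels)
  r <- rle(lab)
  short <- r$values == drinking &
    run_duration_s(r$lengths, spec, sampling_rate) < min_duration_s
  r$values[short] <- other
  lab <- inverse.rle(r)
  if (was_factor) factor(lab, levels = lv) else lab
}

#' Extract contiguous events from a window label sequence
#'
#' Scans the label sequence for maximal runs of the requested class and
#' returns one event per run, with window indices (0-based, inclusive),
#' the covered sample range `[start_sample, end_sample)` and the event
#' duration `((n - 1) * step + window_size) / sampling_rate` in seconds.
#'
#' @param labels Per-window labels.
#' @param spec The `window_spec` the labels were produced under.
#' @param sampling_rate Samples per second.
#' @param class_label Event class to extract (default the drinking label).
#' @return Data frame with columns `first_window`, `last_window`, `class`,
#'   `duration_s`, `start_sample`, `end_sample`; zero rows if the class
#'   never occurs.
#' @export
extract_events <- function(labels, spec, sampling_rate,
                           class_label = DRINKING_LABEL) {
  lab <- as.character(labels)
  empty <- data.frame(first_window = integer(), last_window = integer(),
                      class = character(), duration_s = numeric(),
                      start_sample = integer(), end_sample = integer())
  if (!length(lab)) return(empty)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == class_label
  if (!any(keep)) return(empty)
  first <- starts[keep] - 1L  # 0-based window indices
  last <- ends[keep] - 1L
  data.frame(
    first_window = first,
    last_window = last,
    class = class_label,
    duration_s = run_duration_s(last - first + 1L, spec, sampling_rate),
    start_sample = first * spec$step,
    end_sample = last * spec$step + spec$window_size
  )
}
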