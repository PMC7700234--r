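# Noise reduction and sliding-window segmentation.

#' Trailing moving-average filter
#'
#' Smooths every channel of a recording with a trailing (causal) moving
#' average of `width` samples: the output at index i is the mean of the last
#' `min(width, i + 1)` samples up to and including i (0-based), so the
#' warm-up window shrinks at the start and the recording length is
#' unchanged. The default width of 16 samples corresponds to 125 ms at
#' 128 Hz.
#'
#' @param recording An `imu_recording` (or a plain numeric vector, smoothed
#'   directly).
#' @param width Filter width in samples, >= 1.
#' @return Object of the same type as the input, smoothed.
#' @export
moving_average <- function(recording, width = 16L) {
  if (!is.numeric(width) || length(width) != 1L || width < 1) {
    stop("`width` must be a single integer >= 1", call. = FALSE)
  }
  width <- as.integer(width)
  if (is.numeric(recording)) return(moving_average_vec(recording, width))
  stopifnot(inherits(recording, "imu_recording"))
  out <- recording
  for (ch in IMU_CHANNELS) {
    out$samples[[ch]] <- moving_average_vec(recording$samples[[ch]], width)
  }
  out
}

moving_average_vec <- function(x, width) {
  n <- length(x)
  if (n == 0L) return(x)
  s <- cumsum(x)
  i <- seq_len(n)
  y <- numeric(n)
  head_part <- i <= width
  y[head_part] <- s[head_part] / i[head_part]
  if (any(!head_part)) {
    j <- i[!head_part]
    y[!head_part] <- (s[j] - s[j - width]) / width
  }
  y
}

#' Sliding-window specification
#'
#' A window specification fixes the window size in samples and the fraction
#' of overlap between consecutive windows; the hop is
#' `step = round(window_size * (1 - overlap_fraction))`. The drinking
#' detector defaults to 160 samples with 50% overlap; gesture spotting to
#' 16 samples with 50% overlap.
#'
#' @param window_size Window length in samples, >= 2.
#' @param overlap_fraction Overlap in `[0, 1)`; 0.25, 0.5 and 0.75 are the
#'   usual choices.
#' @return An object of class `window_spec` with fields `window_size`,
#'   `overlap_fraction`, `step`.
#' @export
window_spec <- function(window_size, overlap_fraction = 0.5) {
  if (!is.numeric(window_size) || length(window_size) != 1L ||
      window_size < 2) {
    stop("`window_size` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(overlap_fraction) || length(overlap_fraction) != 1L ||
      overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("`overlap_fraction` must lie in [0, 1)", call. = FALSE)
  }
  window_size <- as.integer(window_size)
  step <- as.integer(round(window_size * (1 - overlap_fraction)))
  if (step < 1L) stop("window step rounds to < 1 sample", call. = FALSE)
  structure(list(window_size = window_size,
                 overlap_fraction = overlap_fraction, step = step),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %d samples, %.0f%% overlap (step %d)\n",
              x$window_size, 100 * x$overlap_fraction, x$step))
  invisible(x)
}

#' Number of sliding windows over a signal
#' @param n_samples Signal length in samples.
#' @param spec A `window_spec`.
#' @return Integer window count `floor((n - W) / step) + 1`.
#' @export
n_windows <- function(n_samples, spec) {
  if (n_samples < spec$window_size) return(0L)
  as.integer((n_samples - spec$window_size) %/% spec$step + 1L)
}

# Per-sample label vector for a recording: OTHER_LABEL outside annotated
# intervals. 1-based vector; interval [start, end) covers start+1 .. end.
sample_labels <- function(n, track) {
  lab <- rep(OTHER_LABEL, n)
  if (!is.null(track) && nrow(track)) {
    for (i in seq_len(nrow(track))) {
      lab[(track$start[i] + 1L):track$end[i]] <- track$label[i]
    }
  }
  lab
}

# Majority label of each window over a per-sample label vector; ties go to
# the label of the window's first sample.
majority_labels <- function(sample_lab, starts, window_size) {
  f <- factor(sample_lab)
  codes <- as.integer(f)
  vapply(starts, function(s) {
    idx <- (s + 1L):(s + window_size)
    cnt <- tabulate(codes[idx], nbins = nlevels(f))
    top <- which(cnt == max(cnt))
    if (length(top) == 1L) levels(f)[top] else sample_lab[s + 1L]
  }, character(1))
}

#' Segment a recording into sliding windows
#'
#' Windows start at `k * step` for `k = 0 .. floor((N - W) / step)`;
#' trailing samples that do not fill a further window are dropped. When an
#' annotation track is given, each window's ground-truth label is the label
#' covering the majority of its samples (samples outside every interval
#' count as `"Other"`); ties go to the label of the window's first sample.
#'
#' @param recording An `imu_recording` (or an integer sample count when only
#'   window geometry is needed).
#' @param spec A `window_spec`.
#' @param annotation Optional `annotation_track` supplying ground truth.
#' @return A data frame of class `window_segments` with columns `start`
#'   (0-based first sample) and `true_label`, and attributes `spec`,
#'   `sampling_rate`, `n_samples`.
#' @export
segment <- function(recording, spec, annotation = NULL) {
  stopifnot(inherits(spec, "window_spec"))
  if (inherits(recording, "imu_recording")) {
    n <- length(recording)
    rate <- recording$sampling_rate
  } else {
    n <- as.integer(recording)
    rate <- DEFAULT_SAMPLING_RATE
  }
  if (n < spec$window_size) {
    stop("recording shorter than one window (", n, " < ", spec$window_size,
         ")", call. = FALSE)
  }
  k <- 0:((n - spec$window_size) %/% spec$step)
  starts <- k * spec$step
  true_label <- rep(NA_character_, length(starts))
  if (!is.null(annotation)) {
    lab <- sample_labels(n, annotation)
    true_label <- majority_labels(lab, starts, spec$window_size)
  }
  structure(data.frame(start = starts, true_label = true_label,
                       stringsAsFactors = FALSE),
            class = c("window_segments", "data.frame"),
            spec = spec, sampling_rate = rate, n_samples = n)
}
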