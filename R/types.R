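#' Construct an IMU recording
#'
#' An IMU recording holds a continuous six-channel inertial stream from a
#' wrist-worn sensor: tri-axial acceleration (`ax`, `ay`, `az`, in G) and
#' tri-axial angular velocity (`wx`, `wy`, `wz`, in deg/s), sampled at a
#' fixed rate (128 Hz by default).
#'
#' Values are validated against the sensor's full-scale ranges
#' (+/-16 G, +/-2000 deg/s); out-of-range or non-finite samples are
#' rejected rather than clipped, so upstream generation or parsing bugs
#' surface immediately.
#'
#' @param subject_id,trial_id Opaque identifier strings.
#' @param samples Data frame with numeric columns `ax, ay, az, wx, wy, wz`,
#'   one row per sample.
#' @param sampling_rate Samples per second; must be positive.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(subject_id, trial_id, samples,
                          sampling_rate = DEFAULT_SAMPLING_RATE) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.character(trial_id), length(trial_id) == 1L)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  samples <- as.data.frame(samples)
  missing_ch <- setdiff(IMU_CHANNELS, names(samples))
  if (length(missing_ch)) {
    stop("missing IMU channel column(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  samples <- samples[IMU_CHANNELS]
  if (nrow(samples) < 1L) stop("recording must contain at least one sample",
                               call. = FALSE)
  validate_frames(samples)
  structure(
    list(subject_id = subject_id, trial_id = trial_id,
         sampling_rate = sampling_rate, samples = samples),
    class = "imu_recording"
  )
}

# Check finiteness and sensor range of a frame table; error with the first
# offending row index.
validate_frames <- function(samples) {
  m <- as.matrix(samples[IMU_CHANNELS])
  bad <- which(!is.finite(m))
  if (length(bad)) {
    row <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    stop("non-finite sensor value at row ", row, call. = FALSE)
  }
  acc <- abs(m[, c("ax", "ay", "az"), drop = FALSE])
  if (any(acc > ACCEL_RANGE_G)) {
    row <- which(apply(acc > ACCEL_RANGE_G, 1L, any))[1L]
    stop("acceleration exceeds +/-", ACCEL_RANGE_G, " G at row ", row,
         call. = FALSE)
  }
  gyr <- abs(m[, c("wx", "wy", "wz"), drop = FALSE])
  if (any(gyr > GYRO_RANGE_DPS)) {
    row <- which(apply(gyr > GYRO_RANGE_DPS, 1L, any))[1L]
    stop("angular velocity exceeds +/-", GYRO_RANGE_DPS, " deg/s at row ",
         row, call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject %s trial %s: %d samples @ %g Hz (%.2f s)\n",
              x$subject_id, x$trial_id, nrow(x$samples), x$sampling_rate,
              nrow(x$samples) / x$sampling_rate))
  invisible(x)
}

#' @export
length.imu_recording <- function(x) nrow(x$samples)

#' Construct an annotation track
#'
#' A track is an ordered set of non-overlapping half-open labeled intervals
#' `[start, end)` over the samples of one recording, at either the activity
#' level (activities of daily living plus the four fluid-intake events) or
#' the gesture level (the five drinking sub-gestures Fetch, Lift, Sip, Drop,
#' Release). Sample indices are 0-based; `end` is exclusive. Fluid-intake
#' intervals carry the container type as metadata in a `container` column.
#'
#' @param recording The `imu_recording` the intervals refer to.
#' @param level `"activity"` or `"gesture"`.
#' @param intervals Data frame with integer columns `start`, `end`, a
#'   character `label` column, and (optionally) `container`.
#' @return An object of class `annotation_track` (a data frame of intervals
#'   with attributes `level`, `subject_id`, `trial_id`, `n_samples`,
#'   `sampling_rate`).
#' @export
annotation_track <- function(recording, level = c("activity", "gesture"),
                             intervals) {
  level <- match.arg(level)
  stopifnot(inherits(recording, "imu_recording"))
  intervals <- as.data.frame(intervals)
  need <- c("start", "end", "label")
  if (!all(need %in% names(intervals))) {
    stop("intervals need columns start, end, label", call. = FALSE)
  }
  if (!"container" %in% names(intervals)) {
    intervals$container <- NA_character_
  }
  intervals <- intervals[c("start", "end", "label", "container")]
  n <- length(recording)
  if (nrow(intervals)) {
    intervals <- intervals[order(intervals$start), , drop = FALSE]
    rownames(intervals) <- NULL
    if (any(intervals$start < 0) || any(intervals$end > n)) {
      stop("interval outside recording bounds [0, ", n, ")", call. = FALSE)
    }
    if (any(intervals$end <= intervals$start)) {
      stop("empty or inverted interval (end <= start)", call. = FALSE)
    }
    if (nrow(intervals) > 1L &&
        any(intervals$start[-1L] < intervals$end[-nrow(intervals)])) {
      stop("overlapping intervals in annotation track", call. = FALSE)
    }
    valid <- c(ACTIVITY_LABELS, GESTURE_LABELS, OTHER_LABEL)
    if (!all(intervals$label %in% valid)) {
      stop("unknown interval label(s): ",
           paste(setdiff(intervals$label, valid), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(intervals, class = c("annotation_track", "data.frame"),
            level = level, subject_id = recording$subject_id,
            trial_id = recording$trial_id, n_samples = n,
            sampling_rate = recording$sampling_rate)
}

#' Assemble a dataset of recordings, annotations and intake amounts
#'
#' A dataset bundles one recording per (subject, trial), one activity-level
#' annotation track per recording, gesture-level tracks covering each
#' fluid-intake interval, and a table of per-drink intake amounts in grams.
#' Recording keys are `"<subject_id>/<trial_id>"`.
#'
#' @param recordings Named list of `imu_recording` objects.
#' @param activity_tracks,gesture_tracks Named lists of `annotation_track`
#'   objects, keyed like `recordings`.
#' @param amounts Data frame with columns `subject_id`, `trial_id`,
#'   `fi_label`, `container`, `start`, `end`, `actual_g` and optionally
#'   `estimated_g`.
#' @return An object of class `intake_dataset`.
#' @export
intake_dataset <- function(recordings, activity_tracks, gesture_tracks,
                           amounts) {
  keys <- names(recordings)
  stopifnot(!is.null(keys), all(nzchar(keys)))
  if (!setequal(keys, names(activity_tracks))) {
    stop("every recording needs exactly one activity track", call. = FALSE)
  }
  amounts <- as.data.frame(amounts)
  need <- c("subject_id", "trial_id", "fi_label", "container", "start",
            "end", "actual_g")
  if (!all(need %in% names(amounts))) {
    stop("amounts table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"estimated_g" %in% names(amounts)) amounts$estimated_g <- NA_real_
  if (nrow(amounts)) {
    if (any(!is.finite(amounts$actual_g)) || any(amounts$actual_g <= 0)) {
      stop("actual_g must be finite and > 0", call. = FALSE)
    }
    if (!all(amounts$container %in% CONTAINERS)) {
      stop("unknown container in amounts table", call. = FALSE)
    }
    # every amount record must match exactly one FI interval of its recording
    for (i in seq_len(nrow(amounts))) {
      key <- paste(amounts$subject_id[i], amounts$trial_id[i], sep = "/")
      tr <- activity_tracks[[key]]
      if (is.null(tr)) stop("amount record for unknown recording ", key,
                            call. = FALSE)
      hit <- tr$label == amounts$fi_label[i] & tr$start == amounts$start[i] &
        tr$end == amounts$end[i]
      if (sum(hit) != 1L) {
        stop("amount record ", i, " does not match exactly one FI interval",
             call. = FALSE)
      }
    }
  }
  structure(
    list(recordings = recordings, activity_tracks = activity_tracks,
         gesture_tracks = gesture_tracks, amounts = amounts),
    class = "intake_dataset"
  )
}

#' @export
print.intake_dataset <- function(x, ...) {
  subs <- unique(vapply(x$recordings, function(r) r$subject_id, character(1)))
  cat(sprintf("<intake_dataset> %d recordings, %d subjects, %d drinks\n",
              length(x$recordings), length(subs), nrow(x$amounts)))
  invisible(x)
}

#' Subject identifiers of a dataset
#' @param dataset An `intake_dataset`.
#' @return Character vector of unique subject ids, in first-appearance order.
#' @export
dataset_subjects <- function(dataset) {
  unique(vapply(dataset$recordings, function(r) r$subject_id, character(1)))
}

#' Leave-one-subject-out folds
#'
#' Splits the subjects of a dataset into leave-one-subject-out (LOSO)
#' cross-validation folds: one fold per subject, in which that subject is
#' the test set and all remaining subjects form the training set. The folds
#' partition the subjects; no training set ever contains its own test
#' subject.
#'
#' @param x An `intake_dataset` or a character vector of subject ids.
#' @return List of folds, each `list(train = <chr>, test = <chr 1>)`.
#' @export
loso_split <- function(x) {
  subjects <- if (inherits(x, "intake_dataset")) dataset_subjects(x)
              else unique(as.character(x))
  if (length(subjects) < 2L) {
    stop("LOSO requires at least 2 subjects", call. = FALSE)
  }
  lapply(subjects, function(s) {
    list(train = setdiff(subjects, s), test = s)
  })
}
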