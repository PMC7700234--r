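# On-disk formats:
#  * sensor stream: CSV with columns t,ax,ay,az,wx,wy,wz, one row per sample,
#    preceded by '#'-comment header lines carrying subject/trial/sampling rate;
#  * annotations and amounts: JSON sidecars per recording.

#' Write an IMU recording to CSV
#'
#' Writes one row per sample with a time column `t = index / sampling_rate`
#' and the six sensor channels, preceded by comment lines
#' `# subject_id:`, `# trial_id:`, `# sampling_rate:`. Values are printed
#' with 17 significant digits so that a write/read round trip reproduces the
#' recording at full double precision.
#'
#' @param recording An `imu_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "imu_recording"))
  s <- recording$samples
  n <- nrow(s)
  t <- (seq_len(n) - 1L) / recording$sampling_rate
  header <- c(
    sprintf("# subject_id: %s", recording$subject_id),
    sprintf("# trial_id: %s", recording$trial_id),
    sprintf("# sampling_rate: %.17g", recording$sampling_rate),
    paste(c("t", IMU_CHANNELS), collapse = ",")
  )
  num <- cbind(t, as.matrix(s))
  body <- do.call(paste, c(lapply(seq_len(ncol(num)), function(j) {
    sprintf("%.17g", num[, j])
  }), sep = ","))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an IMU recording from CSV
#'
#' Inverse of [write_recording()]. The header must name all six channels;
#' subject, trial and sampling rate are taken from the comment lines.
#' Non-finite values or values outside the sensor ranges are rejected with
#' the offending row index.
#'
#' @param path CSV file written by [write_recording()] (or compatible).
#' @return An `imu_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, n = 64L)
  meta <- function(key, default = NA_character_) {
    hit <- grep(sprintf("^#\\s*%s:", key), lines, value = TRUE)
    if (!length(hit)) return(default)
    sub(sprintf("^#\\s*%s:\\s*", key), "", hit[1L])
  }
  subject_id <- meta("subject_id", "unknown")
  trial_id <- meta("trial_id", "unknown")
  rate <- suppressWarnings(as.numeric(meta("sampling_rate")))
  if (!is.finite(rate)) {
    stop("header does not state a sampling rate: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = TRUE)
  missing_ch <- setdiff(IMU_CHANNELS, names(df))
  if (length(missing_ch)) {
    stop("missing channel column(s) in ", path, ": ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  imu_recording(subject_id, trial_id, df[IMU_CHANNELS], sampling_rate = rate)
}

#' Write an annotation track to JSON
#' @param track An `annotation_track`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(track, path) {
  stopifnot(inherits(track, "annotation_track"))
  obj <- list(
    subject_id = attr(track, "subject_id"),
    trial_id = attr(track, "trial_id"),
    level = attr(track, "level"),
    intervals = as.data.frame(unclass(track), stringsAsFactors = FALSE)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read an annotation track from JSON
#'
#' Intervals are re-validated against the recording on read: they must be
#' in-bounds, non-empty and non-overlapping (touching half-open intervals
#' are allowed).
#'
#' @param path JSON file written by [write_annotations()].
#' @param recording The `imu_recording` the intervals refer to.
#' @return An `annotation_track`.
#' @export
read_annotations <- function(path, recording) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  iv <- as.data.frame(obj$intervals)
  if (!nrow(iv)) iv <- data.frame(start = integer(), end = integer(),
                                  label = character())
  annotation_track(recording, level = obj$level, intervals = iv)
}

#' Write per-drink intake amounts to JSON
#' @param amounts Data frame in the layout of `intake_dataset()$amounts`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_amounts <- function(amounts, path) {
  jsonlite::write_json(list(amounts = as.data.frame(amounts)), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read per-drink intake amounts from JSON
#' @param path JSON file written by [write_amounts()].
#' @return Data frame of amount records.
#' @export
read_amounts <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- as.data.frame(obj$amounts)
  if (!"estimated_g" %in% names(df)) df$estimated_g <- NA_real_
  df
}

recording_key <- function(recording) {
  paste(recording$subject_id, recording$trial_id, sep = "/")
}

key_to_stem <- function(key) gsub("/", "_", key, fixed = TRUE)

#' Write a whole dataset to a directory
#'
#' Lays out one `<subject>_<trial>.csv` stream plus `_activity.json` /
#' `_gesture.json` sidecars per recording, a shared `amounts.json`, and an
#' `index.json` listing the recording keys.
#'
#' @param dataset An `intake_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "intake_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keys <- names(dataset$recordings)
  for (key in keys) {
    stem <- file.path(dir, key_to_stem(key))
    write_recording(dataset$recordings[[key]], paste0(stem, ".csv"))
    write_annotations(dataset$activity_tracks[[key]],
                      paste0(stem, "_activity.json"))
    if (!is.null(dataset$gesture_tracks[[key]])) {
      write_annotations(dataset$gesture_tracks[[key]],
                        paste0(stem, "_gesture.json"))
    }
  }
  write_amounts(dataset$amounts, file.path(dir, "amounts.json"))
  jsonlite::write_json(list(recordings = keys), file.path(dir, "index.json"),
                       auto_unbox = FALSE)
  invisible(dir)
}

#' Read a dataset from a directory written by [write_dataset()]
#' @param dir Dataset directory.
#' @return An `intake_dataset`.
#' @export
read_dataset <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"),
                             simplifyVector = TRUE)
  keys <- idx$recordings
  recordings <- list(); act <- list(); ges <- list()
  for (key in keys) {
    stem <- file.path(dir, key_to_stem(key))
    rec <- read_recording(paste0(stem, ".csv"))
    recordings[[key]] <- rec
    act[[key]] <- read_annotations(paste0(stem, "_activity.json"), rec)
    gpath <- paste0(stem, "_gesture.json")
    if (file.exists(gpath)) ges[[key]] <- read_annotations(gpath, rec)
  }
  intake_dataset(recordings, act, ges, read_amounts(file.path(dir, "amounts.json")))
}

#' Export detected events or spotted gestures in the annotation dialect
#'
#' Writes a JSON sidecar in the same dialect as [write_annotations()]:
#' detected drinking events (from [extract_events()]) become intervals
#' labeled with their class; a `gesture_sequence` (from [spot_gestures()])
#' is first collapsed into maximal same-label runs.
#'
#' @param x Event data frame from [extract_events()] or a
#'   `gesture_sequence`.
#' @param path Output file path.
#' @param subject_id,trial_id Identifiers recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path, subject_id = "unknown",
                         trial_id = "unknown") {
  if (inherits(x, "gesture_sequence")) {
    spec <- attr(x, "spec")
    r <- rle(x$label)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    iv <- data.frame(
      start = x$start[starts],
      end = x$start[stops] + spec$window_size,
      label = r$values
    )
    level <- "gesture"
  } else {
    iv <- data.frame(start = x$start_sample, end = x$end_sample,
                     label = x$class)
    level <- "activity"
  }
  obj <- list(subject_id = subject_id, trial_id = trial_id, level = level,
              intervals = iv)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
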