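# Derived signal axes and the 88/89-dimensional statistical feature scheme.
#
# Eleven axes: the six raw channels, the Euclidean norms of the acceleration
# and angular-velocity vectors, and the acceleration magnitudes in the
# horizontal (xy), coronal (yz) and sagittal (xz) planes. Eight statistics
# per axis (mean, sd, variance, max, min, range, kurtosis, skewness) give 88
# features; amount estimation appends the sip duration in seconds as the
# 89th.

#' Derived magnitude axes of an IMU frame table
#'
#' Computes, per sample, the Euclidean norm of the acceleration vector, the
#' Euclidean norm of the angular-velocity vector, and the norms of the
#' acceleration projected onto the xy (horizontal), yz (coronal) and xz
#' (sagittal) planes:
#' \deqn{a_{norm}=\sqrt{a_x^2+a_y^2+a_z^2},\quad
#'       \omega_{norm}=\sqrt{\omega_x^2+\omega_y^2+\omega_z^2},\quad
#'       a_{norm,xy}=\sqrt{a_x^2+a_y^2},\ \ldots}
#'
#' @param frames Data frame with the six IMU channels (non-empty).
#' @return Data frame with columns `a_norm`, `w_norm`, `a_norm_xy`,
#'   `a_norm_yz`, `a_norm_xz`.
#' @export
derive_axes <- function(frames) {
  frames <- as.data.frame(frames)
  if (!nrow(frames)) stop("`frames` must be non-empty", call. = FALSE)
  ax <- frames$ax; ay <- frames$ay; az <- frames$az
  data.frame(
    a_norm = sqrt(ax^2 + ay^2 + az^2),
    w_norm = sqrt(frames$wx^2 + frames$wy^2 + frames$wz^2),
    a_norm_xy = sqrt(ax^2 + ay^2),
    a_norm_yz = sqrt(ay^2 + az^2),
    a_norm_xz = sqrt(ax^2 + az^2)
  )
}

#' Canonical feature names
#'
#' Statistic-major, axis-minor ordering: all means first (over
#' ax, ay, az, wx, wy, wz, a_norm, w_norm, a_norm_xy, a_norm_yz, a_norm_xz),
#' then standard deviations, and so on through skewness; with
#' `include_duration = TRUE` the sip duration is appended as the 89th name.
#'
#' @param include_duration Append `"duration"` as the final feature?
#' @return Character vector of length 88 or 89.
#' @export
feature_names <- function(include_duration = FALSE) {
  nm <- as.vector(t(outer(STAT_ORDER, AXIS_ORDER, paste, sep = "_")))
  if (include_duration) nm <- c(nm, "duration")
  nm
}

# 11-column channel matrix (raw + derived axes) in canonical order.
channel_matrix <- function(frames) {
  frames <- as.data.frame(frames)
  d <- derive_axes(frames)
  m <- cbind(as.matrix(frames[IMU_CHANNELS]), as.matrix(d))
  colnames(m) <- AXIS_ORDER
  m
}

# Vectorised extraction over many windows of one frame table.
# `starts` are 0-based window starts; returns an n_windows x 88 matrix.
# Moments use the population (n-denominator) convention; kurtosis is
# non-excess (normal -> 3); zero-variance windows get kurtosis = skewness
# = 0 so every vector stays finite.
extract_features_matrix <- function(frames, starts, window_size) {
  chan <- channel_matrix(frames)
  nwin <- length(starts)
  W <- as.integer(window_size)
  idx <- outer(seq_len(W), as.integer(starts), `+`)  # W x nwin, 1-based
  out <- matrix(NA_real_, nrow = nwin, ncol = 8L * ncol(chan))
  for (a in seq_len(ncol(chan))) {
    M <- matrix(chan[, a][idx], nrow = W)
    mu <- colMeans(M)
    C <- M - rep(mu, each = W)
    m2 <- colMeans(C * C)
    m3 <- colMeans(C * C * C)
    m4 <- colMeans(C * C * C * C)
    mx <- apply(M, 2L, max)
    mn <- apply(M, 2L, min)
    zero_var <- m2 <= 1e-20
    kur <- ifelse(zero_var, 0, m4 / m2^2)
    ske <- ifelse(zero_var, 0, m3 / m2^1.5)
    stats <- cbind(mu, sqrt(m2), m2, mx, mn, mx - mn, kur, ske)
    out[, (seq_len(8L) - 1L) * ncol(chan) + a] <- stats
  }
  colnames(out) <- feature_names()
  out
}

#' Extract the 88 statistical window features
#'
#' Computes the eight statistics (mean, standard deviation, variance,
#' maximum, minimum, range, kurtosis, skewness) of each of the eleven axes
#' over one window of samples, in canonical order (see [feature_names()]).
#' Variance and standard deviation use the population (n) denominator;
#' kurtosis is non-excess; windows with zero variance on an axis get
#' kurtosis and skewness 0 by convention so downstream models always see
#' finite values.
#'
#' @param frames Frame table of the window; at least 2 rows.
#' @return Named numeric vector of length 88.
#' @export
extract_window_features <- function(frames) {
  frames <- as.data.frame(frames)
  if (nrow(frames) < 2L) {
    stop("feature window needs at least 2 samples", call. = FALSE)
  }
  drop(extract_features_matrix(frames, 0L, nrow(frames)))
}

#' Extract the 89 sip features
#'
#' The 88 window statistics over the whole sip segment plus the sip
#' duration in seconds as the final feature, the only time-domain feature
#' of the amount-estimation scheme.
#'
#' @param frames Frame table of the sip segment; at least 2 rows.
#' @param duration_s Sip duration in seconds, > 0.
#' @return Named numeric vector of length 89.
#' @export
extract_sip_features <- function(frames, duration_s) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0) {
    stop("`duration_s` must be a single positive number", call. = FALSE)
  }
  c(extract_window_features(frames), duration = duration_s)
}

#' Feature matrix for a set of window segments
#'
#' Convenience wrapper applying [extract_window_features()] to every window
#' of a [segment()] result in one vectorised pass.
#'
#' @param recording The (typically smoothed) `imu_recording`.
#' @param segments A `window_segments` data frame from [segment()].
#' @return Numeric matrix, one row per window, 88 named columns.
#' @export
window_feature_matrix <- function(recording, segments) {
  spec <- attr(segments, "spec")
  extract_features_matrix(recording$samples, segments$start,
                          spec$window_size)
}
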