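# Shared constants: label sets, axis ordering, sensor limits.

#' @keywords internal
ACTIVITY_LABELS <- c("A", "C", "H", "S", "FI_1", "FI_2", "FI_3", "FI_4")

#' @keywords internal
GESTURE_LABELS <- c("Fetch", "Lift", "Sip", "Drop", "Release")

#' @keywords internal
OTHER_LABEL <- "Other"

#' @keywords internal
DRINKING_LABEL <- "Drinking"

#' @keywords internal
FI_LABELS <- c("FI_1", "FI_2", "FI_3", "FI_4")

#' @keywords internal
CONTAINERS <- c("can", "bottle", "handleless_mug", "handled_mug")

# Fixed mapping from fluid-intake slot in the protocol to container type.
#' @keywords internal
FI_CONTAINER <- c(
  FI_1 = "can", FI_2 = "bottle",
  FI_3 = "handleless_mug", FI_4 = "handled_mug"
)

#' @keywords internal
IMU_CHANNELS <- c("ax", "ay", "az", "wx", "wy", "wz")

# Canonical axis order for feature extraction: the six raw channels, the
# acceleration and angular-velocity magnitudes, then the three planar
# acceleration magnitudes (horizontal xy, coronal yz, sagittal xz).
#' @keywords internal
AXIS_ORDER <- c(
  "ax", "ay", "az", "wx", "wy", "wz",
  "a_norm", "w_norm", "a_norm_xy", "a_norm_yz", "a_norm_xz"
)

#' @keywords internal
STAT_ORDER <- c(
  "mean", "sd", "variance", "max", "min", "range", "kurtosis", "skewness"
)

# Sensor full-scale ranges: +/-16 G accelerometer, +/-2000 deg/s gyroscope.
#' @keywords internal
ACCEL_RANGE_G <- 16

#' @keywords internal
GYRO_RANGE_DPS <- 2000

#' @keywords internal
DEFAULT_SAMPLING_RATE <- 128

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible 31-bit sub-seed from a root seed and integer tags.
# Simple multiplicative hash; documented so any sub-stream can be replayed.
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (k in c(...)) {
    h <- (h * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
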