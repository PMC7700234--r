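# Synthetic wrist-IMU cohort generator.
#
# Emulates a scripted laboratory protocol: each subject performs five trials
# of a fixed activity sequence (answer phone, comb hair, eat with hands, eat
# with a spoon, and four fluid-intake events with can / plastic bottle /
# handleless mug / handled mug), separated by short idle gaps. Every
# fluid-intake event decomposes into the Fetch-Lift-Sip-Drop-Release
# sub-gestures, and the ingested amount is generated as
# sip_rate[container] * sip_duration * (1 + noise), bounded by the water
# remaining in the container (containers are refilled before the fourth
# trial).
#
# Signal model: each activity is a set of raised-cosine angular-velocity
# bumps on activity-specific axes. Wrist pitch and roll are the discrete
# integrals of the corresponding gyro channels, and the accelerometer
# channels are the gravity vector expressed in the rotated sensor frame (so
# the noise-free acceleration norm is exactly 1 G), plus additive Gaussian
# tremor. Templates aim at statistical separability under the window
# features, not at biomechanical realism: the spoon activity reuses
# lift-tilt-return cycles close to the drinking pattern and is the designed
# hardest confounder.

#' Subject movement profile
#'
#' Per-subject simulation parameters: overall movement speed and amplitude
#' multipliers, tremor noise level, the per-container sip rate in grams of
#' water per second of sip, and the coefficient of variation of the
#' per-drink amount noise.
#'
#' @param subject_id Identifier string.
#' @param movement_speed_scale,amplitude_scale Positive multipliers on
#'   activity tempo and gesture amplitude.
#' @param tremor_sd Additive tremor standard deviation on the accelerometer
#'   channels, in G (the gyro channels get `100 * tremor_sd` deg/s).
#' @param sip_rate Named positive vector of grams/second for the four
#'   containers.
#' @param sip_rate_noise_cv Coefficient of variation of the multiplicative
#'   per-drink amount noise.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id,
                            movement_speed_scale = 1,
                            amplitude_scale = 1,
                            tremor_sd = 0.02,
                            sip_rate = c(can = 14, bottle = 20,
                                         handleless_mug = 10,
                                         handled_mug = 22),
                            sip_rate_noise_cv = 0.10) {
  stopifnot(movement_speed_scale > 0, amplitude_scale > 0, tremor_sd >= 0,
            sip_rate_noise_cv >= 0)
  if (!all(CONTAINERS %in% names(sip_rate)) || any(sip_rate[CONTAINERS] <= 0)) {
    stop("`sip_rate` needs a positive rate for each of the four containers",
         call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id),
                 movement_speed_scale = movement_speed_scale,
                 amplitude_scale = amplitude_scale,
                 tremor_sd = tremor_sd,
                 sip_rate = sip_rate[CONTAINERS],
                 sip_rate_noise_cv = sip_rate_noise_cv),
            class = "subject_profile")
}

#' Draw a cohort of subject profiles from the meta-distribution
#'
#' Subjects differ by modest speed and amplitude multipliers (normal around
#' 1, sd 0.06, clamped to \[0.8, 1.2\]), tremor level (uniform 0.012-0.028 G)
#' and log-normal per-container sip-rate multipliers (sd 0.03 on the log
#' scale), so leave-one-subject-out evaluation sees genuinely unseen
#' parameter combinations while container rates stay well separated and
#' the per-drink amount noise (CV 0.10) remains the dominant error floor
#' of amount estimation.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @return List of `subject_profile` objects named `S01`, `S02`, ...
#' @export
draw_subject_profiles <- function(n, seed) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      base <- c(can = 14, bottle = 20, handleless_mug = 10, handled_mug = 22)
      subject_profile(
        subject_id = sprintf("S%02d", i),
        movement_speed_scale = min(max(stats::rnorm(1, 1, 0.06), 0.8), 1.2),
        amplitude_scale = min(max(stats::rnorm(1, 1, 0.06), 0.8), 1.2),
        tremor_sd = stats::runif(1, 0.012, 0.028),
        sip_rate = base * exp(stats::rnorm(4, 0, 0.03)),
        sip_rate_noise_cv = 0.10
      )
    }) -> profs
    names(profs) <- vapply(profs, `[[`, character(1), "subject_id")
    profs
  })
}

#' Protocol script of the simulated study
#'
#' The activity order of one trial, the trial and subject counts, and the
#' container bookkeeping: capacities and initial fills in grams
#' (240/240, 330/330, 280/320, 300/430 for can, bottle, handleless mug and
#' handled mug). Water is consumed across trials by subtraction and the
#' containers are refilled to the initial level before the fourth trial.
#'
#' @param activities Activity order of one trial; `FI_1`..`FI_4` are the
#'   four fluid-intake events (can, bottle, handleless mug, handled mug).
#' @param trials Trials per subject.
#' @param n_subjects Number of subjects.
#' @param capacity_g,initial_fill_g Named gram vectors per container.
#' @return An object of class `protocol_script`.
#' @export
protocol_script <- function(activities = c("A", "FI_1", "C", "FI_2", "H",
                                           "FI_3", "S", "FI_4", "A"),
                            trials = 5L,
                            n_subjects = 20L,
                            capacity_g = c(can = 240, bottle = 330,
                                           handleless_mug = 320,
                                           handled_mug = 430),
                            initial_fill_g = c(can = 240, bottle = 330,
                                               handleless_mug = 280,
                                               handled_mug = 300)) {
  if (!length(activities)) stop("activity list must be non-empty",
                                call. = FALSE)
  if (!all(activities %in% ACTIVITY_LABELS)) {
    stop("unknown activity label(s): ",
         paste(setdiff(activities, ACTIVITY_LABELS), collapse = ", "),
         call. = FALSE)
  }
  fi <- intersect(activities, FI_LABELS)
  if (!all(fi %in% names(FI_CONTAINER))) {
    stop("every FI label must map to a container", call. = FALSE)
  }
  stopifnot(trials >= 1L, n_subjects >= 1L,
            all(CONTAINERS %in% names(capacity_g)),
            all(CONTAINERS %in% names(initial_fill_g)),
            all(initial_fill_g[CONTAINERS] > 0),
            all(initial_fill_g[CONTAINERS] <= capacity_g[CONTAINERS]))
  structure(list(activities = activities, trials = as.integer(trials),
                 n_subjects = as.integer(n_subjects),
                 capacity_g = capacity_g[CONTAINERS],
                 initial_fill_g = initial_fill_g[CONTAINERS]),
            class = "protocol_script")
}

# ---- signal templates -------------------------------------------------

# Split n samples into parts proportional to `props` (each part >= 1).
split_lengths <- function(n, props) {
  k <- length(props)
  raw <- floor(n * props / sum(props))
  raw <- pmax(raw, 1L)
  while (sum(raw) > n) raw[which.max(raw)] <- raw[which.max(raw)] - 1L
  raw[k] <- raw[k] + (n - sum(raw))
  as.integer(raw)
}

# Raised-cosine angular-rate bump over n samples whose discrete integral
# (sum / fs) equals `angle_deg` exactly.
bump_rate <- function(n, angle_deg, fs) {
  shape <- 1 - cos(2 * pi * (seq_len(n) - 0.5) / n)
  shape * angle_deg * fs / sum(shape)
}

# Small 3 Hz roll adjustment while the container hovers at the mouth;
# mean-subtracted so the net roll stays exactly zero. Distinguishes the
# hover (container being positioned) from the truly static sip plateau.
hover_wiggle <- function(n, fs, amp) {
  if (n < 2L) return(numeric(n))
  w <- 25 * amp * sin(2 * pi * 5 * seq_len(n) / fs)
  w - mean(w)
}

SYNTH_LABELS <- c("A", "C", "H", "S", OTHER_LABEL, GESTURE_LABELS)

# Noise-free gyro template for one activity segment: n x 3 (wx, wy, wz)
# in deg/s. All pitch/roll bumps are discretely normalised so the net tilt
# of every self-contained activity returns exactly to its starting value.
# `drink_tilt` is the per-drink sip tilt angle (deg) shared by Lift and
# Drop so the drinking event closes back to zero pitch; `reach` scales the
# yaw swing of Fetch/Release per drink; `hover` is the per-drink fraction
# of the Lift / Drop phases spent hovering with the container near the
# mouth at 70% of the sip tilt (raising it, pausing, then tipping to
# drink -- and the reverse on the way down).
gyro_template <- function(label, n, fs, amp = 1, drink_tilt = 50,
                          reach = 1, hover = c(0.3, 0.3)) {
  g <- matrix(0, nrow = n, ncol = 3L,
              dimnames = list(NULL, c("wx", "wy", "wz")))
  if (label == "A") {               # answer phone: lift high, sustained hold
    p <- split_lengths(n, c(0.25, 0.5, 0.25))
    g[seq_len(p[1]), "wy"] <- bump_rate(p[1], 80 * amp, fs)
    g[p[1] + p[2] + seq_len(p[3]), "wy"] <- bump_rate(p[3], -80 * amp, fs)
  } else if (label == "C") {        # comb hair: raise, roll oscillation
    p <- split_lengths(n, c(0.2, 0.6, 0.2))
    g[seq_len(p[1]), "wy"] <- bump_rate(p[1], 60 * amp, fs)
    tt <- seq_len(p[2]) / fs
    osc <- 200 * amp * sin(2 * pi * 2 * tt)
    g[p[1] + seq_len(p[2]), "wx"] <- osc - mean(osc)
    g[p[1] + p[2] + seq_len(p[3]), "wy"] <- bump_rate(p[3], -60 * amp, fs)
  } else if (label == "H") {        # eat with hands: 3 short lift cycles
    p <- split_lengths(n, rep(1, 3))
    off <- 0L
    for (ci in 1:3) {
      q <- split_lengths(p[ci], c(1, 1))
      g[off + seq_len(q[1]), "wy"] <- bump_rate(q[1], 45 * amp, fs)
      g[off + q[1] + seq_len(q[2]), "wy"] <- bump_rate(q[2], -45 * amp, fs)
      off <- off + p[ci]
    }
  } else if (label == "S") {        # eat with spoon: 2 lift-hold-return
    p <- split_lengths(n, rep(1, 2)) # cycles; designed nearest confounder
    off <- 0L
    for (ci in 1:2) {
      q <- split_lengths(p[ci], c(0.4, 0.2, 0.4))
      g[off + seq_len(q[1]), "wy"] <- bump_rate(q[1], 50 * amp, fs)
      g[off + q[1] + q[2] + seq_len(q[3]), "wy"] <- bump_rate(q[3], -50 * amp, fs)
      off <- off + p[ci]
    }
  } else if (label == "Fetch") {    # reach out: yaw swing, small pitch dip
    q <- split_lengths(n, c(1, 1))
    g[, "wz"] <- bump_rate(n, 40 * amp * reach, fs)
    g[seq_len(q[1]), "wy"] <- bump_rate(q[1], 12 * amp, fs)
    g[q[1] + seq_len(q[2]), "wy"] <- bump_rate(q[2], -12 * amp, fs)
  } else if (label == "Lift") {     # raise, hover at the mouth, tip to drink
    hf <- min(max(hover[1L], 0), 0.8)
    p <- split_lengths(n, c(0.5 * (1 - hf), hf, 0.5 * (1 - hf)))
    g[seq_len(p[1]), "wy"] <- bump_rate(p[1], 0.7 * drink_tilt * amp, fs)
    g[p[1] + seq_len(p[2]), "wx"] <- hover_wiggle(p[2], fs, amp)
    g[p[1] + p[2] + seq_len(p[3]), "wy"] <-
      bump_rate(p[3], 0.3 * drink_tilt * amp, fs)
  } else if (label == "Sip") {      # near-static tilted plateau
    # all zeros
  } else if (label == "Drop") {     # un-tip, hover, lower back to the table
    hf <- min(max(hover[2L], 0), 0.8)
    p <- split_lengths(n, c(0.5 * (1 - hf), hf, 0.5 * (1 - hf)))
    g[seq_len(p[1]), "wy"] <- bump_rate(p[1], -0.3 * drink_tilt * amp, fs)
    g[p[1] + seq_len(p[2]), "wx"] <- hover_wiggle(p[2], fs, amp)
    g[p[1] + p[2] + seq_len(p[3]), "wy"] <-
      bump_rate(p[3], -0.7 * drink_tilt * amp, fs)
  } else if (label == "Release") {  # return the hand: reverse yaw swing
    q <- split_lengths(n, c(1, 1))
    g[, "wz"] <- bump_rate(n, -40 * amp * reach, fs)
    g[seq_len(q[1]), "wy"] <- bump_rate(q[1], -10 * amp, fs)
    g[q[1] + seq_len(q[2]), "wy"] <- bump_rate(q[2], 10 * amp, fs)
  } else if (label == OTHER_LABEL) {
    # idle: all zeros
  } else {
    stop("unknown activity label '", label, "'", call. = FALSE)
  }
  g
}

# Gravity in the sensor frame given the gyro history: pitch/roll are the
# discrete integrals of wy/wx. Exact unit norm by construction.
gravity_from_gyro <- function(gyro, fs, pitch0 = 0, roll0 = 0) {
  d2r <- pi / 180
  pitch <- (pitch0 + cumsum(gyro[, "wy"]) / fs) * d2r
  roll <- (roll0 + cumsum(gyro[, "wx"]) / fs) * d2r
  cbind(ax = -sin(pitch),
        ay = sin(roll) * cos(pitch),
        az = cos(roll) * cos(pitch))
}

#' Synthesise the wrist-IMU signal of one activity
#'
#' Generates `round(duration_s * fs)` frames of the activity's noise-free
#' angular-velocity template (raised-cosine bumps on activity-specific
#' axes), derives the accelerometer channels as the gravity vector in the
#' sensor frame obtained by integrating wrist pitch and roll from the gyro
#' (so the noise-free acceleration norm is exactly 1 G), and adds Gaussian
#' tremor of sd `tremor_sd` G to the accelerometer and `100 * tremor_sd`
#' deg/s to the gyroscope.
#'
#' Recognised labels: the confounder activities `A`, `C`, `H`, `S`, idle
#' `Other`, and the drinking sub-gestures `Fetch`, `Lift`, `Sip`, `Drop`,
#' `Release` (a full drinking event is the concatenation of the five).
#'
#' @param label Activity or gesture label.
#' @param duration_s Positive duration in seconds.
#' @param profile A `subject_profile`.
#' @param seed Optional integer seed for the tremor noise.
#' @param fs Sampling rate in Hz.
#' @param tilt0 Numeric `c(pitch, roll)` starting tilt in degrees (e.g. the
#'   sip plateau starts at the tilt the Lift gesture ends on).
#' @return Frame data frame (`ax..wz`) with attribute `final_tilt`.
#' @export
synth_activity_signal <- function(label, duration_s, profile, seed = NULL,
                                  fs = DEFAULT_SAMPLING_RATE,
                                  tilt0 = c(pitch = 0, roll = 0)) {
  stopifnot(inherits(profile, "subject_profile"))
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be positive", call. = FALSE)
  }
  n <- as.integer(round(duration_s * fs))
  if (n < 2L) stop("degenerate duration: fewer than 2 samples", call. = FALSE)
  gyro <- gyro_template(label, n, fs, amp = profile$amplitude_scale)
  acc <- gravity_from_gyro(gyro, fs, pitch0 = tilt0[[1L]],
                           roll0 = tilt0[[2L]])
  final_tilt <- c(
    pitch = tilt0[[1L]] + sum(gyro[, "wy"]) / fs,
    roll = tilt0[[2L]] + sum(gyro[, "wx"]) / fs
  )
  add_noise <- function() {
    sdg <- profile$tremor_sd
    acc <- acc + matrix(stats::rnorm(3L * n, 0, sdg), ncol = 3L)
    gyro <- gyro + matrix(stats::rnorm(3L * n, 0, sdg * 100), ncol = 3L)
    data.frame(ax = acc[, 1L], ay = acc[, 2L], az = acc[, 3L],
               wx = gyro[, 1L], wy = gyro[, 2L], wz = gyro[, 3L])
  }
  frames <- if (is.null(seed)) add_noise() else with_seed(seed, add_noise())
  attr(frames, "final_tilt") <- final_tilt
  frames
}

# ---- cohort generation ------------------------------------------------

# Durations (seconds) drawn per activity instance; confounders are scaled
# by the subject's movement speed, the sip keeps its own independent draw
# because it carries the amount information.
draw_activity_durations <- function(label, speed) {
  if (label %in% FI_LABELS) {
    # container-handling tempo varies widely between drinks, so the
    # total activity duration is a poor proxy for the sip duration
    c(Fetch = stats::runif(1, 0.6, 2.0) / speed,
      Lift = stats::runif(1, 0.8, 2.4) / speed,
      Sip = stats::runif(1, 1.5, 3.5),
      Drop = stats::runif(1, 0.8, 2.4) / speed,
      Release = stats::runif(1, 0.6, 2.0) / speed)
  } else {
    switch(label,
           A = stats::runif(1, 5, 7) / speed,
           C = stats::runif(1, 4, 6) / speed,
           H = stats::runif(1, 4, 6) / speed,
           S = stats::runif(1, 4, 6) / speed)
  }
}

#' Generate a labeled synthetic cohort
#'
#' Builds one recording per (subject, trial) following the protocol script:
#' idle gaps of 1-3 s between activities, activity-level annotation for
#' every scripted activity, gesture-level annotation tiling each
#' fluid-intake interval with Fetch, Lift, Sip, Drop, Release, and one
#' amount record per drink with
#' `actual_g = sip_rate[container] * sip_duration * (1 + e)`,
#' `e ~ Normal(0, sip_rate_noise_cv)`, truncated to stay positive and
#' within the water remaining in the container. Fill levels carry across
#' trials and are refilled before the fourth trial. The whole cohort is a
#' deterministic function of `seed`: profiles are drawn from one derived
#' sub-seed and every (subject, trial) consumes its own derived sub-stream.
#'
#' @param script A `protocol_script`.
#' @param seed Integer root seed.
#' @param profiles Optional pre-built list of `subject_profile`s (defaults
#'   to [draw_subject_profiles()] under the derived profile seed).
#' @param fs Sampling rate in Hz.
#' @return An `intake_dataset`.
#' @export
generate_cohort <- function(script = protocol_script(), seed = 1L,
                            profiles = NULL, fs = DEFAULT_SAMPLING_RATE) {
  stopifnot(inherits(script, "protocol_script"))
  if (is.null(profiles)) {
    profiles <- draw_subject_profiles(script$n_subjects, derive_seed(seed, 0L))
  }
  stopifnot(length(profiles) == script$n_subjects)
  recordings <- list(); act_tracks <- list(); ges_tracks <- list()
  amount_rows <- list()
  for (si in seq_len(script$n_subjects)) {
    prof <- profiles[[si]]
    fill <- script$initial_fill_g
    for (ti in seq_len(script$trials)) {
      if (ti == 4L) fill <- script$initial_fill_g  # refill before trial 4
      trial <- with_seed(derive_seed(seed, si, ti), {
        build_trial(script, prof, fill, fs)
      })
      fill <- trial$fill
      key <- paste(prof$subject_id, sprintf("T%d", ti), sep = "/")
      rec <- imu_recording(prof$subject_id, sprintf("T%d", ti),
                           trial$frames, sampling_rate = fs)
      recordings[[key]] <- rec
      act_tracks[[key]] <- annotation_track(rec, "activity", trial$activity_iv)
      ges_tracks[[key]] <- annotation_track(rec, "gesture", trial$gesture_iv)
      if (nrow(trial$amounts)) {
        trial$amounts$subject_id <- prof$subject_id
        trial$amounts$trial_id <- sprintf("T%d", ti)
        amount_rows[[length(amount_rows) + 1L]] <- trial$amounts
      }
    }
  }
  amounts <- do.call(rbind, amount_rows)
  amounts <- amounts[c("subject_id", "trial_id", "fi_label", "container",
                       "start", "end", "actual_g")]
  intake_dataset(recordings, act_tracks, ges_tracks, amounts)
}

# One trial: concatenated gyro templates -> single integration pass ->
# tremor noise. Returns frames, interval tables, amounts and updated fills.
build_trial <- function(script, prof, fill, fs) {
  speed <- prof$movement_speed_scale
  gyro_parts <- list()
  activity_iv <- list(); gesture_iv <- list(); amounts <- list()
  pos <- 0L  # 0-based sample cursor
  push_gap <- function() {
    n <- as.integer(round(stats::runif(1, 1, 3) * fs))
    gyro_parts[[length(gyro_parts) + 1L]] <<-
      gyro_template(OTHER_LABEL, n, fs, prof$amplitude_scale)
    pos <<- pos + n
  }
  push_gap()
  for (act in script$activities) {
    if (act %in% FI_LABELS) {
      durs <- draw_activity_durations(act, speed)
      ns <- pmax(as.integer(round(durs * fs)), 2L)
      names(ns) <- names(durs)
      # wrist inclination, reach amplitude and at-the-mouth hover time all
      # vary drink to drink
      drink_tilt <- 50 * stats::runif(1, 0.8, 1.2)
      reach <- stats::runif(1, 0.6, 1.4)
      hover <- stats::runif(2, 0.1, 0.55)
      fi_start <- pos
      for (ph in GESTURE_LABELS) {
        n <- ns[[ph]]
        gyro_parts[[length(gyro_parts) + 1L]] <-
          gyro_template(ph, n, fs, prof$amplitude_scale,
                        drink_tilt = drink_tilt, reach = reach,
                        hover = hover)
        gesture_iv[[length(gesture_iv) + 1L]] <-
          data.frame(start = pos, end = pos + n, label = ph)
        pos <- pos + n
      }
      container <- FI_CONTAINER[[act]]
      sip_dur <- ns[["Sip"]] / fs  # realized duration in seconds
      if (sip_dur <= 0) stop("degenerate sip duration", call. = FALSE)
      eps <- stats::rnorm(1, 0, prof$sip_rate_noise_cv)
      amt <- prof$sip_rate[[container]] * sip_dur * (1 + eps)
      if (amt <= 0) amt <- 0.05 * prof$sip_rate[[container]] * sip_dur
      if (fill[[container]] <= 0) {
        stop("generation error: container '", container,
             "' is empty before a scheduled drink", call. = FALSE)
      }
      amt <- min(amt, fill[[container]])
      fill[[container]] <- fill[[container]] - amt
      activity_iv[[length(activity_iv) + 1L]] <-
        data.frame(start = fi_start, end = pos, label = act,
                   container = container)
      amounts[[length(amounts) + 1L]] <-
        data.frame(fi_label = act, container = container,
                   start = fi_start, end = pos, actual_g = amt)
    } else {
      dur <- draw_activity_durations(act, speed)
      n <- max(as.integer(round(dur * fs)), 2L)
      gyro_parts[[length(gyro_parts) + 1L]] <-
        gyro_template(act, n, fs, prof$amplitude_scale)
      activity_iv[[length(activity_iv) + 1L]] <-
        data.frame(start = pos, end = pos + n, label = act,
                   container = NA_character_)
      pos <- pos + n
    }
    push_gap()
  }
  gyro <- do.call(rbind, gyro_parts)
  acc <- gravity_from_gyro(gyro, fs)
  n_tot <- nrow(gyro)
  sdg <- prof$tremor_sd
  acc <- acc + matrix(stats::rnorm(3L * n_tot, 0, sdg), ncol = 3L)
  gyro <- gyro + matrix(stats::rnorm(3L * n_tot, 0, sdg * 100), ncol = 3L)
  frames <- data.frame(ax = acc[, 1L], ay = acc[, 2L], az = acc[, 3L],
                       wx = gyro[, 1L], wy = gyro[, 2L], wz = gyro[, 3L])
  list(frames = frames,
       activity_iv = do.call(rbind, activity_iv),
       gesture_iv = do.call(rbind, gesture_iv),
       amounts = if (length(amounts)) do.call(rbind, amounts) else
         data.frame(fi_label = character(), container = character(),
                    start = integer(), end = integer(),
                    actual_g = numeric()),
       fill = fill)
}
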