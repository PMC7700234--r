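test_that("default protocol yields the full scripted cohort structure", {
  sc <- protocol_script()
  expect_equal(length(sc$activities) * sc$trials * sc$n_subjects, 900L)
  expect_equal(sc$initial_fill_g,
               c(can = 240, bottle = 330, handleless_mug = 280,
                 handled_mug = 300))
  expect_error(protocol_script(activities = character(0)), "non-empty")
  expect_error(protocol_script(activities = c("A", "FI_9")), "unknown")
})

test_that("cohort generation is bit-identical under the same seed", {
  sc <- protocol_script(n_subjects = 2L, trials = 2L)
  d1 <- generate_cohort(sc, seed = 123L)
  d2 <- generate_cohort(sc, seed = 123L)
  expect_identical(d1, d2)
  d3 <- generate_cohort(sc, seed = 124L)
  expect_false(identical(d1$recordings[[1]]$samples,
                         d3$recordings[[1]]$samples))
})

test_that("gesture sub-intervals exactly tile every FI interval, in order", {
  ds <- tiny_cohort()
  for (key in names(ds$recordings)) {
    at <- ds$activity_tracks[[key]]
    gt <- ds$gesture_tracks[[key]]
    fi <- at[at$label %in% c("FI_1", "FI_2", "FI_3", "FI_4"), ]
    for (i in seq_len(nrow(fi))) {
      sub <- gt[gt$start >= fi$start[i] & gt$end <= fi$end[i], ]
      expect_equal(sub$label, c("Fetch", "Lift", "Sip", "Drop", "Release"))
      expect_equal(sub$start[1], fi$start[i])
      expect_equal(sub$end[5], fi$end[i])
      expect_equal(sub$start[-1], sub$end[-5])  # contiguous tiling
      sip <- sub[sub$label == "Sip", ]
      expect_gt(sip$end - sip$start, 0)
    }
  }
})

test_that("amounts follow rate x duration within the noise model and fills", {
  sc <- protocol_script(n_subjects = 4L, trials = 5L)
  seed <- 77L
  profiles <- draw_subject_profiles(4L, fluidintake:::derive_seed(seed, 0L))
  ds <- generate_cohort(sc, seed = seed, profiles = profiles)
  am <- ds$amounts
  fs <- 128
  for (i in seq_len(nrow(am))) {
    key <- paste(am$subject_id[i], am$trial_id[i], sep = "/")
    gt <- ds$gesture_tracks[[key]]
    sip <- gt[gt$label == "Sip" & gt$start >= am$start[i] &
                gt$end <= am$end[i], ]
    dur <- (sip$end - sip$start) / fs
    rate <- profiles[[am$subject_id[i]]]$sip_rate[[am$container[i]]]
    # |eps| < 6 sd almost surely; truncation only lowers the amount
    expect_lt(am$actual_g[i], rate * dur * 1.6)
    expect_gt(am$actual_g[i], 0)
  }
  # per-container regression of amount on true sip duration recovers the
  # rate within the noise CV
  for (ctn in unique(am$container)) {
    sel <- am$container == ctn
    durs <- vapply(which(sel), function(i) {
      key <- paste(am$subject_id[i], am$trial_id[i], sep = "/")
      gt <- ds$gesture_tracks[[key]]
      sip <- gt[gt$label == "Sip" & gt$start >= am$start[i] &
                  gt$end <= am$end[i], ]
      (sip$end - sip$start) / fs
    }, numeric(1))
    slope <- coef(lm(am$actual_g[sel] ~ durs + 0))[[1]]
    mean_rate <- mean(vapply(profiles, function(p) p$sip_rate[[ctn]],
                             numeric(1)))
    expect_lt(abs(slope - mean_rate) / mean_rate, 0.10)
  }
  # fills: total per container per subject within trials 1-3 never exceeds
  # the initial fill (refill happens before trial 4)
  for (s in unique(am$subject_id)) {
    for (ctn in unique(am$container)) {
      pre <- am$actual_g[am$subject_id == s & am$container == ctn &
                           am$trial_id %in% c("T1", "T2", "T3")]
      expect_lte(sum(pre), sc$initial_fill_g[[ctn]] + 1e-9)
    }
  }
})

test_that("noise-free signals obey the gravity and template closed forms", {
  p <- default_profile(tremor_sd = 0)
  # Sip phase: static tilted posture, acceleration norm exactly 1 G
  f <- synth_activity_signal("Sip", 2, p, seed = 1L, tilt0 = c(50, 0))
  anorm <- sqrt(f$ax^2 + f$ay^2 + f$az^2)
  expect_equal(anorm, rep(1, nrow(f)), tolerance = 1e-12)
  expect_true(all(f$wx == 0 & f$wy == 0 & f$wz == 0))
  # any phase: gyro equals the closed-form template exactly
  f2 <- synth_activity_signal("Lift", 1, p, seed = 1L)
  tmpl <- fluidintake:::gyro_template("Lift", nrow(f2), 128, 1)
  expect_equal(f2$wy, tmpl[, "wy"], tolerance = 1e-12)
  expect_equal(sum(f2$wy) / 128, 50)  # integrates to the sip tilt angle
  expect_equal(sqrt(f2$ax^2 + f2$ay^2 + f2$az^2), rep(1, nrow(f2)),
               tolerance = 1e-12)
  # self-contained activities return to zero tilt
  for (lab in c("A", "C", "H", "S")) {
    fa <- synth_activity_signal(lab, 5, p, seed = 2L)
    expect_equal(unname(attr(fa, "final_tilt")), c(0, 0), tolerance = 1e-9)
  }
  expect_error(synth_activity_signal("jumping", 1, p), "unknown activity")
  expect_error(synth_activity_signal("A", 0, p), "positive")
})

test_that("tremor noise model: mean acceleration norm near 1 G when idle", {
  p <- default_profile(tremor_sd = 0.05)
  f <- synth_activity_signal("Other", 20, p, seed = 6L)
  anorm <- sqrt(f$ax^2 + f$ay^2 + f$az^2)
  # Monte-Carlo check of the noise model: for gravity plus isotropic
  # N(0, s^2) tremor, E[|a|] ~= 1 + s^2 to second order; the sample mean
  # must sit within 3 standard errors of that expansion.
  se <- sd(anorm) / sqrt(length(anorm))
  expect_lt(abs(mean(anorm) - (1 + 0.05^2)), 3 * se)
})

test_that("generated recordings stay within sensor ranges and validate", {
  ds <- tiny_cohort()
  for (rec in ds$recordings) {
    expect_true(all(abs(as.matrix(rec$samples[, 1:3])) <= 16))
    expect_true(all(abs(as.matrix(rec$samples[, 4:6])) <= 2000))
  }
})
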