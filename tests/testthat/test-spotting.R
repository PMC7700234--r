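test_that("sip extraction applies the run-length duration formula", {
  sp <- window_spec(16L, 0.5)  # step 8
  lab <- c("Fetch", "Lift", "Sip", "Sip", "Drop", "Release")
  sips <- extract_sips(lab, sp, 128)
  expect_equal(nrow(sips), 1L)
  expect_equal(sips$duration_s, (1 * 8 + 16) / 128)  # 0.1875 s
  expect_equal(sips$start, 2L * 8L)
  expect_equal(sips$end, 3L * 8L + 16L)

  expect_equal(nrow(extract_sips(c("Fetch", "Lift", "Drop"), sp, 128)), 0L)

  two <- c("Sip", "Sip", "Lift", "Sip", "Drop")
  sips2 <- extract_sips(two, sp, 128, offset = 100L)
  expect_equal(nrow(sips2), 2L)
  expect_true(all(diff(sips2$start) > 0))       # ordered
  expect_true(all(sips2$start[-1] >= sips2$end[-nrow(sips2)]))  # disjoint
  expect_equal(sips2$start[1], 100L)            # offset applied
})

test_that("five-class fragment revision smooths gesture streams within the alphabet", {
  lab <- c("Fetch", "Fetch", "Sip", "Fetch", "Fetch")
  expect_equal(fragment_revision(lab), rep("Fetch", 5))
  set.seed(10)
  for (i in 1:25) {
    g <- sample(c("Fetch", "Lift", "Sip", "Drop", "Release"), 20,
                replace = TRUE)
    out <- fragment_revision(g)
    expect_true(all(out %in% c("Fetch", "Lift", "Sip", "Drop", "Release")))
  }
})

test_that("spotting a noise-free synthetic drink recovers the gesture sequence", {
  p <- default_profile(tremor_sd = 0.001)
  fs <- 128
  phases <- c(Fetch = 1, Lift = 1, Sip = 2.5, Drop = 1, Release = 1)
  build_drink <- function(seed) {
    tilt <- c(0, 0)
    frames <- list(); labels <- list()
    for (ph in names(phases)) {
      f <- synth_activity_signal(ph, phases[[ph]], p, seed = seed,
                                 tilt0 = tilt)
      tilt <- attr(f, "final_tilt")
      frames[[ph]] <- f
      labels[[ph]] <- rep(ph, nrow(f))
      seed <- seed + 1L
    }
    list(frames = do.call(rbind, frames), labels = unlist(labels))
  }
  sp <- window_spec(16L, 0.5)
  train <- build_drink(100L)
  segs <- segment(nrow(train$frames), sp)
  X <- fluidintake:::extract_features_matrix(train$frames, segs$start, 16L)
  y <- fluidintake:::majority_labels(train$labels, segs$start, 16L)
  clf <- train_detector(X, y, model_name = "rforest", seed = 1L)

  test <- build_drink(200L)
  gseq <- spot_gestures(test$frames, sp, clf, sampling_rate = fs)
  truth <- fluidintake:::majority_labels(test$labels, gseq$start, 16L)
  agree <- mean(gseq$label == truth)
  expect_gt(agree, 0.9)
  sips <- extract_sips(gseq)
  expect_equal(nrow(sips), 1L)
  expect_equal(sips$duration_s, 2.5, tolerance = 0.15)  # one window slack

  expect_error(spot_gestures(test$frames[1:8, ], sp, clf),
               "shorter than one spotting window")
})

test_that("on ground-truth gesture labels, extract_sips recovers annotated sips", {
  ds <- tiny_cohort()
  sp <- window_spec(16L, 0.5)
  key <- names(ds$recordings)[1]
  at <- ds$activity_tracks[[key]]
  gt <- ds$gesture_tracks[[key]]
  fi <- at[at$label %in% c("FI_1", "FI_2", "FI_3", "FI_4"), ]
  for (i in seq_len(nrow(fi))) {
    lo <- fi$start[i]; hi <- fi$end[i]
    rel <- gt[gt$start >= lo & gt$end <= hi, ]
    rel$start <- rel$start - lo; rel$end <- rel$end - lo
    n <- hi - lo
    lab <- fluidintake:::majority_labels(
      fluidintake:::sample_labels(n, rel),
      segment(n, sp)$start, 16L)
    sips <- extract_sips(lab, sp, 128, offset = lo)
    truth <- gt[gt$label == "Sip" & gt$start >= lo & gt$end <= hi, ]
    expect_equal(nrow(sips), 1L)
    # recovered to within one window of quantisation at each edge
    expect_lt(abs(sips$start - truth$start), 16L)
    expect_lt(abs(sips$end - truth$end), 16L)
  }
})

test_that("events and gesture sequences export in the annotation JSON dialect", {
  sp <- window_spec(160L, 0.5)
  ev <- extract_events(c("O", "D", "D", "O"), sp, 128, class_label = "D")
  path <- withr::local_tempfile(fileext = ".json")
  write_events(ev, path, subject_id = "S01", trial_id = "T1")
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$level, "activity")
  expect_equal(back$intervals$start, 80L)
  expect_equal(back$intervals$end, 2 * 80L + 160L)

  g <- structure(data.frame(start = c(0L, 8L, 16L, 24L),
                            label = c("Lift", "Sip", "Sip", "Drop")),
                 class = c("gesture_sequence", "data.frame"),
                 spec = window_spec(16L, 0.5), sampling_rate = 128)
  write_events(g, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$level, "gesture")
  expect_equal(back$intervals$label, c("Lift", "Sip", "Drop"))
  expect_equal(back$intervals$start, c(0L, 8L, 24L))
  expect_equal(back$intervals$end, c(16L, 32L, 40L))
})
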