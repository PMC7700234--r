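test_that("fragment revision reproduces the one- and two-fragment rules", {
  expect_equal(fragment_revision(c("D", "D", "O", "D", "D")),
               c("D", "D", "D", "D", "D"))
  expect_equal(fragment_revision(c("O", "O", "D", "D", "O", "O")),
               c("O", "O", "O", "O", "O", "O"))
  # run of 3 exceeds the rule's scope
  expect_equal(fragment_revision(c("D", "O", "O", "O", "D")),
               c("D", "O", "O", "O", "D"))
  # differing neighbours leave the fragment alone (5-class case)
  expect_equal(fragment_revision(c("Fetch", "Sip", "Lift")),
               c("Fetch", "Sip", "Lift"))
  # edge runs without two-sided neighbours are untouched
  expect_equal(fragment_revision(c("D", "O", "O")), c("D", "O", "O"))
  expect_equal(fragment_revision(character(0)), character(0))
})

test_that("fragment revision never invents labels and preserves factors", {
  set.seed(21)
  for (i in 1:50) {
    lab <- sample(c("D", "O"), 30, replace = TRUE)
    out <- fragment_revision(lab)
    expect_true(all(out %in% lab))
    expect_length(out, length(lab))
  }
  f <- factor(c("F", "F", "S", "F", "F"), levels = c("F", "S", "X"))
  out <- fragment_revision(f)
  expect_s3_class(out, "factor")
  expect_identical(levels(out), c("F", "S", "X"))
  expect_equal(as.character(out), rep("F", 5))
})

test_that("duration threshold removes short drinking runs, boundary kept", {
  sp <- window_spec(160L, 0.5)  # step 80; durations per run length:
  # 1 window -> 160/128 = 1.25 s; 2 -> 1.875 s; 3 -> 2.5 s
  lab <- c("Other", "Drinking", "Other", "Other",
           "Drinking", "Drinking", "Drinking", "Other")
  out <- duration_threshold(lab, sp, 128, min_duration_s = 2)
  expect_equal(out, c("Other", "Other", "Other", "Other",
                      "Drinking", "Drinking", "Drinking", "Other"))
  # exactly 2.0 s survives ("less than" is strict): W=128, step 64, 3 windows
  sp2 <- window_spec(128L, 0.5)
  lab2 <- c("Other", rep("Drinking", 3), "Other")
  expect_equal(duration_threshold(lab2, sp2, 128, 2), lab2)
  # idempotence
  expect_equal(duration_threshold(out, sp, 128, 2), out)
})

test_that("no surviving drinking run is shorter than the threshold", {
  set.seed(33)
  for (thr in c(1, 2)) {
    for (i in 1:40) {
      sp <- window_spec(sample(c(64L, 128L, 160L), 1), 0.5)
      lab <- sample(c("Drinking", "Other"), 40, replace = TRUE)
      out <- duration_threshold(lab, sp, 128, min_duration_s = thr)
      ev <- extract_events(out, sp, 128)
      if (nrow(ev)) expect_true(all(ev$duration_s >= thr))
    }
  }
})

test_that("event extraction matches a brute-force run-length scan", {
  sp <- window_spec(160L, 0.5)
  ev <- extract_events(c("O", "O", "D", "D", "D", "O"), sp, 128,
                       class_label = "D")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$first_window, 2L)
  expect_equal(ev$last_window, 4L)
  expect_equal(ev$duration_s, (2 * 80 + 160) / 128)  # 2.5 s
  expect_equal(ev$start_sample, 160L)
  expect_equal(ev$end_sample, 480L)

  expect_equal(nrow(extract_events(rep("O", 5), sp, 128, "D")), 0L)

  set.seed(7)
  for (i in 1:30) {
    lab <- sample(c("D", "O"), 25, replace = TRUE)
    ev <- extract_events(lab, sp, 128, "D")
    # brute force: scan indices
    runs <- rle(lab)
    stops <- cumsum(runs$lengths)
    starts <- stops - runs$lengths + 1L
    keep <- runs$values == "D"
    expect_equal(ev$first_window, starts[keep] - 1L)
    expect_equal(ev$last_window, stops[keep] - 1L)
  }
})

test_that("all six classifier families separate two Gaussian clouds", {
  set.seed(2)
  n <- 120
  x <- rbind(matrix(rnorm(n * 4, 0), ncol = 4),
             matrix(rnorm(n * 4, 10), ncol = 4))
  y <- rep(c("Drinking", "Other"), each = n)
  xt <- rbind(matrix(rnorm(40 * 4, 0), ncol = 4),
              matrix(rnorm(40 * 4, 10), ncol = 4))
  yt <- rep(c("Drinking", "Other"), each = 40)
  for (m in c("adaboost", "dtree", "rforest", "nbayes", "knn",
              "svm_linear")) {
    clf <- train_detector(x, y, model_name = m, seed = 99L)
    expect_equal(as.character(predict(clf, xt)), yt, label = m)
  }
  expect_error(train_detector(x, rep("D", nrow(x))), "single class")
  expect_error(train_detector(x, y, model_name = "mlp"), "unknown model")
})

test_that("seeded training is deterministic", {
  set.seed(14)
  x <- matrix(rnorm(600), ncol = 6)
  y <- ifelse(rowSums(x) + rnorm(100, 0, 0.5) > 0, "Drinking", "Other")
  for (m in c("adaboost", "rforest")) {
    c1 <- train_detector(x, y, model_name = m, seed = 5L)
    c2 <- train_detector(x, y, model_name = m, seed = 5L)
    expect_identical(predict(c1, x), predict(c2, x), label = m)
  }
})

test_that("pipeline order classify -> revise -> threshold shapes a noisy stream", {
  sp <- window_spec(160L, 0.5)
  # a drinking event interrupted by a one-window fragment, plus an
  # isolated spurious detection elsewhere
  lab <- c("Other", "Other", "Drinking", "Drinking", "Drinking", "Other",
           "Drinking", "Drinking", "Drinking", "Other", "Other", "Other",
           "Drinking", "Other", "Other")
  rev <- fragment_revision(lab)
  out <- duration_threshold(rev, sp, 128, 2)
  ev <- extract_events(out, sp, 128)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$first_window, 2L)
  expect_equal(ev$last_window, 8L)
})
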