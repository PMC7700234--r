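test_that("detection metrics follow the confusion-count formulas", {
  m <- detection_metrics(list(TP = 9, FN = 1, FP = 0, TN = 10))
  expect_equal(m$sensitivity, 90)
  expect_equal(m$precision, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$accuracy, 95)

  perfect <- detection_metrics(list(TP = 5, FN = 0, FP = 0, TN = 5))
  expect_true(all(perfect == 100))

  # zero denominators are undefined, not 0
  und <- detection_metrics(list(TP = 0, FN = 0, FP = 0, TN = 8))
  expect_true(is.na(und$sensitivity))
  expect_true(is.na(und$precision))
  expect_equal(und$specificity, 100)

  set.seed(71)
  for (i in 1:20) {
    cc <- as.list(setNames(sample(1:50, 4), c("TP", "FP", "TN", "FN")))
    m <- detection_metrics(cc)
    expect_equal(m$sensitivity, 100 * cc$TP / (cc$TP + cc$FN))
    expect_equal(m$precision, 100 * cc$TP / (cc$TP + cc$FP))
    expect_equal(m$specificity, 100 * cc$TN / (cc$TN + cc$FP))
    expect_equal(m$accuracy,
                 100 * (cc$TP + cc$TN) / (cc$TP + cc$FP + cc$TN + cc$FN))
  }
})

test_that("confusion counts total the evaluated windows", {
  set.seed(72)
  truth <- sample(c("Drinking", "Other"), 200, replace = TRUE)
  pred <- sample(c("Drinking", "Other"), 200, replace = TRUE)
  cc <- confusion_counts(truth, pred)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 200L)
  expect_error(confusion_counts(truth, pred[-1]), "length")
})

test_that("gesture metrics match a brute-force one-vs-rest oracle", {
  gestures <- c("Fetch", "Lift", "Sip", "Drop", "Release")
  set.seed(73)
  truth <- sample(gestures, 300, replace = TRUE)
  pred <- ifelse(runif(300) < 0.7, truth, sample(gestures, 300, TRUE))
  gm <- gesture_metrics(truth, pred)
  for (g in gestures) {
    tp <- sum(truth == g & pred == g)
    sens <- 100 * tp / sum(truth == g)
    prec <- 100 * tp / sum(pred == g)
    row <- gm$per_gesture[gm$per_gesture$gesture == g, ]
    expect_equal(row$sensitivity, sens)
    expect_equal(row$precision, prec)
  }
  expect_equal(gm$overall[["sensitivity"]],
               mean(gm$per_gesture$sensitivity))

  perfect <- gesture_metrics(truth, truth)
  expect_true(all(perfect$per_gesture$sensitivity == 100))
  expect_equal(unname(perfect$overall), c(100, 100))

  # absent gesture: undefined sensitivity, excluded with a warning
  t2 <- sample(gestures[1:4], 50, replace = TRUE)
  expect_warning(gm2 <- gesture_metrics(t2, t2), "Release")
  expect_true(is.na(gm2$per_gesture$sensitivity[
    gm2$per_gesture$gesture == "Release"]))
  expect_equal(gm2$overall[["sensitivity"]], 100)
})

test_that("amount metrics implement signed and absolute percentage errors", {
  expect_equal(amount_metrics(data.frame(actual_g = 100, estimated_g = 80)),
               data.frame(MPE = 20, MAPE = 20, n = 1L))
  # offsetting signed errors
  m <- amount_metrics(data.frame(actual_g = c(100, 100),
                                 estimated_g = c(80, 120)))
  expect_equal(m$MPE, 0)
  expect_equal(m$MAPE, 20)
  # exact estimates
  m0 <- amount_metrics(data.frame(actual_g = c(50, 60),
                                  estimated_g = c(50, 60)))
  expect_equal(m0$MPE, 0)
  expect_equal(m0$MAPE, 0)
  expect_error(amount_metrics(data.frame(actual_g = numeric(),
                                         estimated_g = numeric())),
               "no estimated")

  # invariants: MAPE >= |MPE|; permutation invariance
  set.seed(74)
  for (i in 1:25) {
    df <- data.frame(actual_g = runif(20, 10, 100),
                     estimated_g = runif(20, 5, 120))
    m <- amount_metrics(df)
    expect_gte(m$MAPE, abs(m$MPE))
    mp <- amount_metrics(df[sample(20), ])
    expect_equal(mp$MPE, m$MPE)
    expect_equal(mp$MAPE, m$MAPE)
  }
})

test_that("hierarchical evaluation produces a coherent report on a micro-cohort", {
  ds <- tiny_cohort()
  rep <- run_hierarchical_eval(ds, eval_config(seed = 11L))
  expect_s3_class(rep, "hier_eval_report")
  # one fold per subject
  expect_equal(nrow(rep$detection$per_fold), 3L)
  # confusion totals = window counts evaluated
  tot <- Reduce(`+`, rep$detection$counts)
  expected_windows <- sum(vapply(ds$recordings, function(r) {
    n_windows(length(r), window_spec(160L, 0.5))
  }, integer(1)))
  expect_equal(tot, expected_windows)
  # amount table has both situations x both scopes, same denominators
  expect_setequal(
    paste(rep$amount_metrics$situation, rep$amount_metrics$scope),
    c("whole_activity independent", "whole_activity dependent",
      "sip_gesture independent", "sip_gesture dependent"))
  expect_equal(length(unique(rep$amount_metrics$n)), 1L)
  expect_equal(rep$event_accounting$n_drinks, nrow(ds$amounts))
  expect_equal(rep$event_accounting$n_matched +
                 rep$event_accounting$n_missed, nrow(ds$amounts))
  # gesture metrics cover the five-gesture alphabet
  expect_equal(nrow(rep$gestures$per_gesture), 5L)
})
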