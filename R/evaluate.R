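# Leave-one-subject-out orchestration: detection-only evaluation,
# estimation-only evaluation on ground-truth boundaries, and the full
# hierarchical run comparing amount estimation from whole drinking
# activities (situation 1) against sip-gesture information (situation 2).

#' Evaluation configuration
#'
#' Bundles every tunable of the hierarchical run. Defaults follow the best
#' reported configurations: AdaBoost detector over 160-sample windows with
#' 50% overlap and a 2-s duration threshold; random-forest gesture spotter
#' over 16-sample windows with 50% overlap; linear-kernel SVM regression
#' for the amount.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param smooth_width Moving-average width in samples.
#' @param detector_model,detector_window,min_duration_s Detection stage.
#' @param detector_hyperparams,spotter_hyperparams Named lists forwarded to
#'   [train_detector()].
#' @param spotter_model,spotter_window Gesture-spotting stage.
#' @param estimator_model Amount-regression family.
#' @param max_spot_train_windows Cap on gesture training windows per fold
#'   (subsampled reproducibly when exceeded).
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(seed = 1L,
                        smooth_width = 16L,
                        detector_model = "adaboost",
                        detector_window = window_spec(160L, 0.5),
                        min_duration_s = 2,
                        detector_hyperparams = list(),
                        spotter_model = "rforest",
                        spotter_window = window_spec(16L, 0.5),
                        spotter_hyperparams = list(),
                        estimator_model = "svm_linear",
                        max_spot_train_windows = 12000L) {
  structure(list(seed = as.integer(seed), smooth_width = smooth_width,
                 detector_model = detector_model,
                 detector_window = detector_window,
                 min_duration_s = min_duration_s,
                 detector_hyperparams = detector_hyperparams,
                 spotter_model = spotter_model,
                 spotter_window = spotter_window,
                 spotter_hyperparams = spotter_hyperparams,
                 estimator_model = estimator_model,
                 max_spot_train_windows = max_spot_train_windows),
            class = "eval_config")
}

smooth_dataset <- function(dataset, width) {
  lapply(dataset$recordings, moving_average, width = width)
}

# Binary per-window detection ground truth for one recording.
binary_window_truth <- function(n, track, starts, window_size) {
  lab <- sample_labels(n, track)
  lab[lab %in% FI_LABELS] <- DRINKING_LABEL
  lab[lab != DRINKING_LABEL] <- OTHER_LABEL
  majority_labels(lab, starts, window_size)
}

# Per-recording detection windows: features + binary truth.
prepare_detection <- function(dataset, smoothed, spec) {
  lapply(names(dataset$recordings), function(key) {
    rec <- smoothed[[key]]
    segs <- segment(rec, spec)
    feats <- extract_features_matrix(rec$samples, segs$start,
                                     spec$window_size)
    truth <- binary_window_truth(length(rec), dataset$activity_tracks[[key]],
                                 segs$start, spec$window_size)
    list(key = key, subject = rec$subject_id, feats = feats, truth = truth)
  }) -> out
  names(out) <- names(dataset$recordings)
  out
}

#' Leave-one-subject-out drinking detection
#'
#' Trains the window classifier on all but one subject, predicts the
#' held-out subject's windows, applies fragment revision and the duration
#' threshold, and accumulates window-level confusion counts per fold.
#'
#' @param dataset An `intake_dataset`.
#' @param config An [eval_config()].
#' @return List with `per_fold` (data frame of per-subject counts and
#'   metrics), `pooled` (metrics over the summed confusion counts),
#'   `counts` (summed counts), and `events` (named list, per recording, of
#'   post-processed detected events).
#' @export
loso_detect <- function(dataset, config = eval_config()) {
  spec <- config$detector_window
  smoothed <- smooth_dataset(dataset, config$smooth_width)
  prep <- prepare_detection(dataset, smoothed, spec)
  folds <- loso_split(dataset)
  fs <- dataset$recordings[[1L]]$sampling_rate
  per_fold <- list(); events <- list()
  total <- list(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    tr <- prep[vapply(prep, `[[`, character(1), "subject") %in% fold$train]
    te <- prep[vapply(prep, `[[`, character(1), "subject") == fold$test]
    clf <- train_detector(do.call(rbind, lapply(tr, `[[`, "feats")),
                          unlist(lapply(tr, `[[`, "truth")),
                          model_name = config$detector_model,
                          hyperparams = config$detector_hyperparams %||% list(),
                          seed = derive_seed(config$seed, fi, 1L))
    cc <- list(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
    for (p in te) {
      pred <- predict(clf, p$feats)
      pred <- fragment_revision(pred)
      pred <- duration_threshold(pred, spec, fs,
                                 min_duration_s = config$min_duration_s)
      one <- confusion_counts(p$truth, pred)
      cc <- Map(`+`, cc, one)
      events[[p$key]] <- extract_events(pred, spec, fs)
    }
    total <- Map(`+`, total, cc)
    per_fold[[fi]] <- cbind(data.frame(subject = fold$test), as.data.frame(cc),
                            detection_metrics(cc))
  }
  list(per_fold = do.call(rbind, per_fold), pooled = detection_metrics(total),
       counts = total, events = events)
}

# 89-feature matrix and aligned amount records from ground-truth sip (or
# whole-activity) boundaries, using the smoothed signal.
ground_truth_drink_features <- function(dataset, smoothed,
                                        use = c("sip", "activity")) {
  use <- match.arg(use)
  am <- dataset$amounts
  fs <- dataset$recordings[[1L]]$sampling_rate
  X <- matrix(NA_real_, nrow = nrow(am), ncol = 89L)
  for (i in seq_len(nrow(am))) {
    key <- paste(am$subject_id[i], am$trial_id[i], sep = "/")
    if (use == "sip") {
      gt <- dataset$gesture_tracks[[key]]
      sip <- gt[gt$label == "Sip" & gt$start >= am$start[i] &
                  gt$end <= am$end[i], , drop = FALSE]
      lo <- sip$start[1L]; hi <- sip$end[1L]
    } else {
      lo <- am$start[i]; hi <- am$end[i]
    }
    frames <- smoothed[[key]]$samples[(lo + 1L):hi, , drop = FALSE]
    X[i, ] <- extract_sip_features(frames, (hi - lo) / fs)
  }
  colnames(X) <- feature_names(include_duration = TRUE)
  list(X = X, amounts = am)
}

#' Leave-one-subject-out amount estimation on ground-truth boundaries
#'
#' Isolates the estimation stage: features are extracted from the
#' annotated sip (or whole drinking-activity) intervals, an estimator of
#' the requested family is trained per LOSO fold -- pooled over containers
#' (independent scope) and separately per container (dependent scope) --
#' and the held-out subject's drinks are predicted.
#'
#' @param dataset An `intake_dataset`.
#' @param model_name Regression family (see [estimator_spec()]).
#' @param use `"sip"` for sip-gesture features (duration = sip duration) or
#'   `"activity"` for whole drinking-activity features.
#' @param smooth_width Moving-average width in samples.
#' @return List with `records` (amount table with `est_independent` and
#'   `est_dependent` columns) and `metrics` (data frame of MPE/MAPE by
#'   scope and container).
#' @export
loso_estimate <- function(dataset, model_name = "svm_linear",
                          use = c("sip", "activity"), smooth_width = 16L) {
  use <- match.arg(use)
  smoothed <- smooth_dataset(dataset, smooth_width)
  gt <- ground_truth_drink_features(dataset, smoothed, use = use)
  am <- gt$amounts
  am$est_independent <- NA_real_
  am$est_dependent <- NA_real_
  for (fold in loso_split(dataset)) {
    tr <- am$subject_id %in% fold$train
    te <- am$subject_id == fold$test
    est_i <- train_estimator(gt$X[tr, , drop = FALSE], am$actual_g[tr],
                             estimator_spec(model_name, "independent"))
    am$est_independent[te] <- estimate_amount(est_i, gt$X[te, , drop = FALSE])
    for (ctn in unique(am$container)) {
      trc <- tr & am$container == ctn
      tec <- te & am$container == ctn
      if (!any(tec)) next
      est_d <- train_estimator(gt$X[trc, , drop = FALSE], am$actual_g[trc],
                               estimator_spec(model_name, "dependent",
                                              container = ctn),
                               containers = am$container[trc])
      am$est_dependent[tec] <- estimate_amount(est_d,
                                               gt$X[tec, , drop = FALSE])
    }
  }
  metrics <- rbind(
    cbind(data.frame(scope = "independent", container = "all"),
          amount_metrics(data.frame(actual_g = am$actual_g,
                                    estimated_g = am$est_independent))),
    cbind(data.frame(scope = "dependent", container = "all"),
          amount_metrics(data.frame(actual_g = am$actual_g,
                                    estimated_g = am$est_dependent))),
    do.call(rbind, lapply(unique(am$container), function(ctn) {
      sel <- am$container == ctn
      cbind(data.frame(scope = "dependent", container = ctn),
            amount_metrics(data.frame(actual_g = am$actual_g[sel],
                                      estimated_g = am$est_dependent[sel])))
    }))
  )
  list(records = am, metrics = metrics)
}

# Gesture-spotting training windows from ground-truth FI intervals.
spotting_windows <- function(dataset, smoothed, spec) {
  out <- list()
  for (key in names(dataset$recordings)) {
    atr <- dataset$activity_tracks[[key]]
    gtr <- dataset$gesture_tracks[[key]]
    fi <- atr[atr$label %in% FI_LABELS, , drop = FALSE]
    if (!nrow(fi)) next
    subj <- dataset$recordings[[key]]$subject_id
    for (i in seq_len(nrow(fi))) {
      lo <- fi$start[i]; hi <- fi$end[i]
      frames <- smoothed[[key]]$samples[(lo + 1L):hi, , drop = FALSE]
      if (nrow(frames) < spec$window_size) next
      segs <- segment(nrow(frames), spec)
      feats <- extract_features_matrix(frames, segs$start, spec$window_size)
      rel <- gtr[gtr$start >= lo & gtr$end <= hi, , drop = FALSE]
      rel$start <- rel$start - lo; rel$end <- rel$end - lo
      lab <- majority_labels(sample_labels(nrow(frames), rel), segs$start,
                             spec$window_size)
      out[[length(out) + 1L]] <- list(key = key, subject = subj,
                                      fi_index = i, feats = feats,
                                      truth = lab)
    }
  }
  out
}

# Greedy matching of detected events to ground-truth FI intervals by
# maximal sample overlap. Returns, per truth interval, the index of its
# best-overlapping event (NA if missed).
match_events <- function(events, fi) {
  if (!nrow(events) || !nrow(fi)) {
    return(list(match = rep(NA_integer_, nrow(fi)),
                false_alarms = seq_len(nrow(events))))
  }
  ov <- outer(seq_len(nrow(fi)), seq_len(nrow(events)),
              Vectorize(function(i, j) {
                max(0L, min(fi$end[i], events$end_sample[j]) -
                      max(fi$start[i], events$start_sample[j]))
              }))
  match <- rep(NA_integer_, nrow(fi))
  taken <- logical(nrow(events))
  for (i in order(-apply(ov, 1L, max))) {
    best <- which.max(ifelse(taken, -1, ov[i, ]))
    if (ov[i, best] > 0 && !taken[best]) {
      match[i] <- best
      taken[best] <- TRUE
    }
  }
  list(match = match, false_alarms = which(!taken))
}

#' Run the full hierarchical evaluation
#'
#' Executes the four pipeline components under leave-one-subject-out cross
#' validation: moving-average smoothing, drinking detection with rule-based
#' modification, gesture spotting inside the detected events, and amount
#' estimation -- in two configurations per drink: situation (1) uses the
#' whole detected drinking activity (its duration substitutes the sip
#' duration), situation (2) uses the spotted sip gesture; each in both
#' container-independent and container-dependent scope. Events whose
#' spotting finds no sip window fall back to whole-event features and are
#' flagged. Detected events are matched to ground-truth drinks by maximal
#' overlap; unmatched truths count as missed, unmatched events as false
#' alarms, and only matched drinks enter the amount metrics (the same
#' denominator for both situations).
#'
#' Amount estimators are trained on *recognized* drink data: every
#' subject's drinks are first processed by a detector and spotter that
#' never saw that subject, and each fold's estimators are then fitted on
#' the recognized features of the training subjects. Training and test
#' features therefore come from the same (pipeline-induced) distribution;
#' training on clean annotated boundaries while predicting pipeline output
#' would let boundary quantisation artifacts dominate the regression. A
#' container whose recognized training drinks are fewer than three falls
#' back to the container-independent estimate for that fold.
#'
#' @param dataset An `intake_dataset`.
#' @param config An [eval_config()].
#' @return List of class `hier_eval_report` with elements `detection`,
#'   `gestures`, `amounts` (per-drink table), `amount_metrics`,
#'   `event_accounting` and `config`.
#' @export
run_hierarchical_eval <- function(dataset, config = eval_config()) {
  fs <- dataset$recordings[[1L]]$sampling_rate
  dspec <- config$detector_window
  sspec <- config$spotter_window
  smoothed <- smooth_dataset(dataset, config$smooth_width)
  prep <- prepare_detection(dataset, smoothed, dspec)
  spot_all <- spotting_windows(dataset, smoothed, sspec)
  am <- dataset$amounts
  res <- am
  res$matched <- FALSE
  res$fallback <- NA
  res$sit1_independent <- NA_real_; res$sit1_dependent <- NA_real_
  res$sit2_independent <- NA_real_; res$sit2_dependent <- NA_real_
  # recognized 89-dim features per drink: whole detected event (situation 1)
  # and spotted sip (situation 2)
  feat1 <- matrix(NA_real_, nrow(am), 89L,
                  dimnames = list(NULL, feature_names(TRUE)))
  feat2 <- feat1
  folds <- loso_split(dataset)
  per_fold <- list()
  total <- list(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  ges_truth <- character(0); ges_pred <- character(0)
  n_false_alarm <- 0L
  subj_of <- vapply(prep, `[[`, character(1), "subject")
  spot_subj <- vapply(spot_all, `[[`, character(1), "subject")
  for (fi_ in seq_along(folds)) {
    fold <- folds[[fi_]]
    ## --- detection ---
    tr <- prep[subj_of %in% fold$train]
    te <- prep[subj_of == fold$test]
    det <- train_detector(do.call(rbind, lapply(tr, `[[`, "feats")),
                          unlist(lapply(tr, `[[`, "truth")),
                          model_name = config$detector_model,
                          hyperparams = config$detector_hyperparams %||% list(),
                          seed = derive_seed(config$seed, fi_, 1L))
    ## --- gesture spotter ---
    sw <- spot_all[spot_subj %in% fold$train]
    sX <- do.call(rbind, lapply(sw, `[[`, "feats"))
    sy <- unlist(lapply(sw, `[[`, "truth"))
    if (nrow(sX) > config$max_spot_train_windows) {
      keep <- with_seed(derive_seed(config$seed, fi_, 2L),
                        sample.int(nrow(sX), config$max_spot_train_windows))
      sX <- sX[keep, , drop = FALSE]; sy <- sy[keep]
    }
    spotter <- train_detector(sX, sy, model_name = config$spotter_model,
                              hyperparams = config$spotter_hyperparams %||% list(),
                              seed = derive_seed(config$seed, fi_, 3L))
    ## --- held-out subject: detect, spot, extract recognized features ---
    cc <- list(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
    for (p in te) {
      pred <- predict(det, p$feats)
      pred <- fragment_revision(pred)
      pred <- duration_threshold(pred, dspec, fs,
                                 min_duration_s = config$min_duration_s)
      cc <- Map(`+`, cc, confusion_counts(p$truth, pred))
      events <- extract_events(pred, dspec, fs)
      atr <- dataset$activity_tracks[[p$key]]
      fi_iv <- atr[atr$label %in% FI_LABELS, , drop = FALSE]
      mm <- match_events(events, fi_iv)
      n_false_alarm <- n_false_alarm + length(mm$false_alarms)
      frames_all <- smoothed[[p$key]]$samples
      for (i in seq_len(nrow(fi_iv))) {
        if (is.na(mm$match[i])) next
        ev <- events[mm$match[i], ]
        ridx <- which(am$subject_id == p$subject &
                        am$trial_id == sub(".*/", "", p$key) &
                        am$start == fi_iv$start[i] & am$end == fi_iv$end[i])
        if (length(ridx) != 1L) next
        lo <- ev$start_sample; hi <- min(ev$end_sample, nrow(frames_all))
        frames <- frames_all[(lo + 1L):hi, , drop = FALSE]
        ## situation 1: whole detected activity
        x1 <- extract_sip_features(frames, (hi - lo) / fs)
        ## situation 2: spotted sip gesture
        fallback <- TRUE
        x2 <- x1
        if (nrow(frames) >= sspec$window_size) {
          gseq <- spot_gestures(frames, sspec, spotter, sampling_rate = fs)
          sips <- extract_sips(gseq)
          if (nrow(sips)) {
            sip_idx <- unlist(lapply(seq_len(nrow(sips)), function(j) {
              (sips$start[j] + 1L):min(sips$end[j], nrow(frames))
            }))
            x2 <- extract_sip_features(frames[sip_idx, , drop = FALSE],
                                       sum(sips$duration_s))
            fallback <- FALSE
          }
        }
        res$matched[ridx] <- TRUE
        res$fallback[ridx] <- fallback
        feat1[ridx, ] <- x1
        feat2[ridx, ] <- x2
      }
    }
    total <- Map(`+`, total, cc)
    per_fold[[fi_]] <- cbind(data.frame(subject = fold$test),
                             as.data.frame(cc), detection_metrics(cc))
    ## --- gesture spotting accuracy on held-out ground-truth segments ---
    for (w in spot_all[spot_subj == fold$test]) {
      gp <- as.character(fragment_revision(predict(spotter, w$feats)))
      ges_truth <- c(ges_truth, w$truth)
      ges_pred <- c(ges_pred, gp)
    }
  }
  ## --- second pass: amount estimation on recognized drink features ---
  ## Every drink's recognized features were produced by models that never
  ## saw its subject, so training fold estimators on the training subjects'
  ## recognized drinks leaks nothing about the held-out subject.
  for (fold in folds) {
    te_r <- which(am$subject_id == fold$test & res$matched)
    tr_r <- which(am$subject_id %in% fold$train & res$matched)
    if (!length(te_r) || length(tr_r) < 3L) next
    for (sit in 1:2) {
      X <- if (sit == 1L) feat1 else feat2
      col_i <- sprintf("sit%d_independent", sit)
      col_d <- sprintf("sit%d_dependent", sit)
      # the sip-feature model is trained on spotted sips only; drinks whose
      # spotting found no sip are estimated with situation-(1) behaviour
      tr_s <- if (sit == 2L) tr_r[!res$fallback[tr_r]] else tr_r
      te_s <- if (sit == 2L) te_r[!res$fallback[te_r]] else te_r
      if (length(tr_s) < 3L || !length(te_s)) next
      est_i <- train_estimator(X[tr_s, , drop = FALSE], am$actual_g[tr_s],
                               estimator_spec(config$estimator_model,
                                              "independent"))
      res[[col_i]][te_s] <- estimate_amount(est_i, X[te_s, , drop = FALSE])
      for (ctn in unique(am$container[te_s])) {
        tec <- te_s[am$container[te_s] == ctn]
        trc <- tr_s[am$container[tr_s] == ctn]
        if (length(trc) < 3L) {
          # too few recognized drinks of this container in training:
          # fall back to the independent-scope estimate
          res[[col_d]][tec] <- res[[col_i]][tec]
          next
        }
        est_d <- train_estimator(X[trc, , drop = FALSE], am$actual_g[trc],
                                 estimator_spec(config$estimator_model,
                                                "dependent",
                                                container = ctn))
        res[[col_d]][tec] <- estimate_amount(est_d, X[tec, , drop = FALSE])
      }
    }
  }
  # fallback drinks inherit their situation-(1) estimates in situation (2)
  fb <- which(res$matched & !is.na(res$fallback) & res$fallback)
  res$sit2_independent[fb] <- res$sit1_independent[fb]
  res$sit2_dependent[fb] <- res$sit1_dependent[fb]
  amount_tbl <- do.call(rbind, lapply(
    c("sit1_independent", "sit1_dependent", "sit2_independent",
      "sit2_dependent"),
    function(col) {
      situation <- if (startsWith(col, "sit1")) "whole_activity" else
        "sip_gesture"
      scope <- sub("sit[12]_", "", col)
      sel <- res$matched
      cbind(data.frame(situation = situation, scope = scope),
            amount_metrics(data.frame(actual_g = res$actual_g[sel],
                                      estimated_g = res[[col]][sel])))
    }))
  structure(list(
    detection = list(pooled = detection_metrics(total), counts = total,
                     per_fold = do.call(rbind, per_fold)),
    gestures = gesture_metrics(ges_truth, ges_pred),
    amounts = res,
    amount_metrics = amount_tbl,
    event_accounting = list(n_drinks = nrow(res),
                            n_matched = sum(res$matched),
                            n_missed = sum(!res$matched),
                            n_false_alarms = n_false_alarm,
                            n_fallback = sum(res$fallback, na.rm = TRUE)),
    config = config
  ), class = "hier_eval_report")
}

#' @export
print.hier_eval_report <- function(x, ...) {
  cat("<hier_eval_report>\n")
  cat("Detection (window level, pooled over LOSO folds):\n")
  print(round(x$detection$pooled, 2))
  cat("Gesture spotting (overall):\n")
  print(round(x$gestures$overall, 2))
  cat("Amount estimation:\n")
  tbl <- x$amount_metrics
  tbl$MPE <- round(tbl$MPE, 2); tbl$MAPE <- round(tbl$MAPE, 2)
  print(tbl)
  acc <- x$event_accounting
  cat(sprintf("Drinks: %d, matched %d, missed %d, false alarms %d, fallback %d\n",
              acc$n_drinks, acc$n_matched, acc$n_missed, acc$n_false_alarms,
              acc$n_fallback))
  invisible(x)
}
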