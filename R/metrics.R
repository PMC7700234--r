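# Evaluation metrics: window-level confusion counts, detection metrics,
# per-gesture one-vs-rest metrics, and amount-estimation percentage errors.

#' Window-level confusion counts
#'
#' @param truth,pred Equal-length label vectors.
#' @param positive The positive-class label (default drinking).
#' @return List with integer fields `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred, positive = DRINKING_LABEL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) {
    stop("truth and prediction differ in length", call. = FALSE)
  }
  t_pos <- truth == positive
  p_pos <- pred == positive
  list(TP = sum(t_pos & p_pos), FP = sum(!t_pos & p_pos),
       TN = sum(!t_pos & !p_pos), FN = sum(t_pos & !p_pos))
}

#' Detection metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`, specificity
#' `TN/(TN+FP)` and accuracy `(TP+TN)/total`, each in percent. A metric
#' whose denominator is zero is undefined and reported as `NA`, never as 0.
#'
#' @param counts List with fields `TP`, `FP`, `TN`, `FN` (as from
#'   [confusion_counts()]).
#' @return One-row data frame with columns `sensitivity`, `precision`,
#'   `specificity`, `accuracy` (percent).
#' @export
detection_metrics <- function(counts) {
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  with(counts, data.frame(
    sensitivity = ratio(TP, TP + FN),
    precision = ratio(TP, TP + FP),
    specificity = ratio(TN, TN + FP),
    accuracy = ratio(TP + TN, TP + FP + TN + FN)
  ))
}

#' Per-gesture and overall spotting metrics
#'
#' One-vs-rest sensitivity and precision for each of the five drinking
#' gestures, plus unweighted overall means. A gesture absent from the
#' ground truth has undefined sensitivity (`NA`, with a warning) and is
#' excluded from the overall mean.
#'
#' @param truth,pred Equal-length gesture label vectors.
#' @param labels Gesture alphabet (default the five drinking gestures).
#' @return List with `per_gesture` (data frame: gesture, sensitivity,
#'   precision) and `overall` (named vector: sensitivity, precision).
#' @export
gesture_metrics <- function(truth, pred, labels = GESTURE_LABELS) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) {
    stop("truth and prediction differ in length", call. = FALSE)
  }
  per <- do.call(rbind, lapply(labels, function(g) {
    cc <- confusion_counts(truth, pred, positive = g)
    m <- detection_metrics(cc)
    data.frame(gesture = g, sensitivity = m$sensitivity,
               precision = m$precision)
  }))
  absent <- !labels %in% truth
  if (any(absent)) {
    warning("gesture(s) absent from ground truth excluded from overall: ",
            paste(labels[absent], collapse = ", "), call. = FALSE)
  }
  keep <- !absent
  overall <- c(
    sensitivity = mean(per$sensitivity[keep], na.rm = TRUE),
    precision = mean(per$precision[keep], na.rm = TRUE)
  )
  list(per_gesture = per, overall = overall)
}

#' Amount-estimation percentage errors
#'
#' Mean percentage error and mean absolute percentage error of the
#' estimated versus actual intake amounts:
#' \deqn{MPE = \frac{1}{n}\sum_i \frac{a_i - e_i}{a_i} \times 100,\qquad
#'       MAPE = \frac{1}{n}\sum_i \left|\frac{a_i - e_i}{a_i}\right|
#'       \times 100.}
#' Positive and negative signed errors can offset each other in MPE; MAPE
#' cannot, so `MAPE >= |MPE|` always.
#'
#' @param records Data frame with columns `actual_g` (> 0) and
#'   `estimated_g`; rows with missing estimates are dropped.
#' @return One-row data frame with columns `MPE`, `MAPE`, `n`.
#' @export
amount_metrics <- function(records) {
  records <- as.data.frame(records)
  records <- records[!is.na(records$estimated_g), , drop = FALSE]
  if (!nrow(records)) stop("no estimated amount records", call. = FALSE)
  if (any(records$actual_g <= 0)) stop("actual_g must be > 0", call. = FALSE)
  rel <- (records$actual_g - records$estimated_g) / records$actual_g
  data.frame(MPE = 100 * mean(rel), MAPE = 100 * mean(abs(rel)),
             n = nrow(records))
}
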