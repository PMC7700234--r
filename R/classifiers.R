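# Window classifiers shared by drinking detection and gesture spotting.
#
# Six model families are supported, mirroring the usual suspects of
# wearable activity recognition: AdaBoost over CART weak learners, a single
# CART decision tree, random forest (minimum leaf size 1), Gaussian naive
# Bayes, k-nearest neighbours (k = 3 for detection, k = 11 for spotting),
# and a linear-kernel SVM.

DETECTOR_MODELS <- c("adaboost", "dtree", "rforest", "nbayes", "knn",
                     "svm_linear")

#' Train a window classifier
#'
#' Fits one of the six supported classifier families on a feature matrix.
#' The same interface serves binary drinking detection and five-class
#' gesture spotting. Defaults: k-NN uses `k = 3`; naive Bayes assumes
#' normal class-conditional feature distributions; the SVM uses a linear
#' kernel; random forest trees are grown to minimum leaf size 1 (minimum
#' parent size 2); AdaBoost boosts depth-limited CART trees with the
#' multi-class SAMME weight update.
#'
#' @param x Numeric feature matrix, one row per window.
#' @param y Class labels (factor or character); at least two classes.
#' @param model_name One of `"adaboost"`, `"dtree"`, `"rforest"`,
#'   `"nbayes"`, `"knn"`, `"svm_linear"`.
#' @param hyperparams Named list of per-model settings: `k` (knn, default
#'   3), `ntree` (rforest, default 100), `nrounds` / `maxdepth` (adaboost,
#'   defaults 30 / 3), `cost` (svm_linear, default 1).
#' @param seed Optional integer seed applied to the stochastic fits
#'   (random forest, boosting), making training reproducible.
#' @return An object of class `intake_classifier` with a [predict] method
#'   returning a factor of predicted labels.
#' @export
train_detector <- function(x, y, model_name = "adaboost",
                           hyperparams = list(), seed = NULL) {
  if (!model_name %in% DETECTOR_MODELS) {
    stop("unknown model_name '", model_name, "'; expected one of: ",
         paste(DETECTOR_MODELS, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  colnames(x) <- make.names(colnames(x) %||% paste0("f", seq_len(ncol(x))))
  fit_fun <- function() {
    switch(model_name,
      adaboost = fit_adaboost(x, y,
                              nrounds = hyperparams$nrounds %||% 30L,
                              maxdepth = hyperparams$maxdepth %||% 3L),
      dtree = rpart::rpart(y ~ ., data = data.frame(y = y, x),
                           method = "class",
                           control = rpart::rpart.control(xval = 0L)),
      rforest = randomForest::randomForest(
        x, y, ntree = hyperparams$ntree %||% 100L,
        nodesize = 1L),
      nbayes = e1071::naiveBayes(x, y),
      knn = fit_knn(x, y, k = hyperparams$k %||% 3L),
      svm_linear = e1071::svm(x, y, kernel = "linear",
                              cost = hyperparams$cost %||% 1,
                              scale = safe_scale(x))
    )
  }
  fit <- if (is.null(seed)) fit_fun() else with_seed(seed, fit_fun())
  structure(list(model_name = model_name, fit = fit, levels = levels(y),
                 features = colnames(x)),
            class = "intake_classifier")
}

# Columns with zero variance cannot be scaled; disable scaling for them.
safe_scale <- function(x) apply(x, 2L, stats::sd) > 0

fit_knn <- function(x, y, k) {
  mu <- colMeans(x)
  sd_ <- apply(x, 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  list(x = scale(x, center = mu, scale = sd_), y = y, k = as.integer(k),
       center = mu, scale = sd_)
}

# AdaBoost (SAMME) over rpart CART weak learners. With K classes the round
# weight is alpha = log((1 - err)/err) + log(K - 1); binary K = 2 reduces to
# the classical AdaBoost.M1 update.
fit_adaboost <- function(x, y, nrounds = 30L, maxdepth = 3L) {
  n <- nrow(x)
  K <- nlevels(y)
  df <- data.frame(y = y, x)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = 0, minsplit = 2L,
                               minbucket = 1L, xval = 0L)
  for (m in seq_len(nrounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w * n, method = "class",
                        control = ctrl)
    pred <- stats::predict(fit, df, type = "class")
    miss <- pred != y
    err <- sum(w[miss])
    if (err >= 1 - 1 / K) break  # weak learner no better than chance
    alpha <- if (err <= 1e-12) {
      log((1 - 1e-12) / 1e-12) + log(K - 1)
    } else {
      log((1 - err) / err) + log(K - 1)
    }
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 1e-12) break  # perfect learner; committee is decided
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (!length(trees)) {
    # fall back to a single unboosted tree
    trees <- list(rpart::rpart(y ~ ., data = df, method = "class",
                               control = ctrl))
    alphas <- 1
  }
  list(trees = trees, alphas = alphas, levels = levels(y))
}

predict_adaboost <- function(fit, newdata) {
  votes <- matrix(0, nrow = nrow(newdata), ncol = length(fit$levels),
                  dimnames = list(NULL, fit$levels))
  df <- data.frame(newdata)
  for (m in seq_along(fit$trees)) {
    p <- as.character(stats::predict(fit$trees[[m]], df, type = "class"))
    votes[cbind(seq_len(nrow(votes)), match(p, fit$levels))] <-
      votes[cbind(seq_len(nrow(votes)), match(p, fit$levels))] + fit$alphas[m]
  }
  factor(fit$levels[max.col(votes, ties.method = "first")],
         levels = fit$levels)
}

#' Predict window labels with a trained classifier
#'
#' @param object An `intake_classifier` from [train_detector()].
#' @param newdata Numeric feature matrix with the training columns.
#' @param ... Unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.intake_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) colnames(newdata) <- object$features
  colnames(newdata) <- make.names(colnames(newdata))
  out <- switch(object$model_name,
    adaboost = predict_adaboost(object$fit, newdata),
    dtree = stats::predict(object$fit, data.frame(newdata), type = "class"),
    rforest = stats::predict(object$fit, newdata),
    nbayes = stats::predict(object$fit, newdata),
    knn = {
      z <- scale(newdata, center = object$fit$center,
                 scale = object$fit$scale)
      class::knn(object$fit$x, z, object$fit$y, k = object$fit$k)
    },
    svm_linear = stats::predict(object$fit, newdata)
  )
  factor(as.character(out), levels = object$levels)
}

#' @export
print.intake_classifier <- function(x, ...) {
  cat(sprintf("<intake_classifier> %s over %d features, classes: %s\n",
              x$model_name, length(x$features),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}
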