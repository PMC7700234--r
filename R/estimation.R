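# Intake-amount regression from sip-gesture features.

ESTIMATOR_MODELS <- c("linear", "gaussian_kernel", "svm_linear", "svm_poly3",
                      "svm_rbf")

#' Specify an amount estimator
#'
#' Fixes the regression family and the training scope: a
#' container-*independent* estimator pools drinks from all containers; a
#' container-*dependent* estimator is trained on drinks from a single known
#' container type (the container is metadata carried with each drink, never
#' inferred from the signal).
#'
#' @param model_name One of `"linear"`, `"gaussian_kernel"`,
#'   `"svm_linear"`, `"svm_poly3"` (polynomial kernel of degree 3),
#'   `"svm_rbf"`.
#' @param scope `"independent"` or `"dependent"`.
#' @param container Required when `scope = "dependent"`; one of the four
#'   container types.
#' @return An object of class `estimator_spec`.
#' @export
estimator_spec <- function(model_name = "svm_linear",
                           scope = c("independent", "dependent"),
                           container = NULL) {
  scope <- match.arg(scope)
  if (!model_name %in% ESTIMATOR_MODELS) {
    stop("unknown model_name '", model_name, "'; expected one of: ",
         paste(ESTIMATOR_MODELS, collapse = ", "), call. = FALSE)
  }
  if (scope == "dependent") {
    if (is.null(container) || !container %in% CONTAINERS) {
      stop("dependent scope requires `container` in: ",
           paste(CONTAINERS, collapse = ", "), call. = FALSE)
    }
  } else {
    container <- NULL
  }
  structure(list(model_name = model_name, scope = scope,
                 container = container),
            class = "estimator_spec")
}

#' Train an intake-amount estimator
#'
#' Fits the requested regression model mapping 89-dimensional sip feature
#' vectors to intake amount in grams. Features are standardised with
#' training-fold mean and standard deviation before the kernel-based models
#' (Nadaraya-Watson and the SVMs); `"gaussian_kernel"` is Nadaraya-Watson
#' kernel regression with a Gaussian kernel and Silverman's rule-of-thumb
#' bandwidth on the standardised features; the SVM regressors are
#' eps-regression with linear, cubic-polynomial or radial-basis kernels at
#' library-default cost and epsilon.
#'
#' @param x Numeric feature matrix (89 columns), one row per drink.
#' @param y Actual intake amounts in grams.
#' @param spec An `estimator_spec`.
#' @param containers Optional character vector of per-row container types;
#'   checked against `spec$container` under dependent scope.
#' @return An object of class `amount_estimator`.
#' @export
train_estimator <- function(x, y, spec = estimator_spec(),
                            containers = NULL) {
  stopifnot(inherits(spec, "estimator_spec"))
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  if (nrow(x) < 3L) stop("need at least 3 training drinks", call. = FALSE)
  if (spec$scope == "dependent" && !is.null(containers) &&
      !all(containers == spec$container)) {
    stop("dependent-scope training rows must all be container '",
         spec$container, "'", call. = FALSE)
  }
  colnames(x) <- make.names(colnames(x) %||% paste0("f", seq_len(ncol(x))))
  fit <- switch(spec$model_name,
    linear = {
      df <- data.frame(y = y, x)
      suppressWarnings(stats::lm(y ~ ., data = df))
    },
    gaussian_kernel = fit_nw(x, y),
    svm_linear = suppressWarnings(
      e1071::svm(x, y, type = "eps-regression", kernel = "linear",
                 scale = safe_scale(x))),
    svm_poly3 = suppressWarnings(
      e1071::svm(x, y, type = "eps-regression", kernel = "polynomial",
                 degree = 3L, scale = safe_scale(x))),
    svm_rbf = suppressWarnings(
      e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                 scale = safe_scale(x)))
  )
  structure(list(spec = spec, fit = fit, features = colnames(x),
                 p = ncol(x)),
            class = "amount_estimator")
}

# Nadaraya-Watson Gaussian kernel regression on standardised features.
# Scalar bandwidth by Silverman's rule-of-thumb (unit-sd features).
fit_nw <- function(x, y) {
  mu <- colMeans(x)
  sd_ <- apply(x, 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  z <- scale(x, center = mu, scale = sd_)
  n <- nrow(x); d <- ncol(x)
  h <- (4 / (d + 2))^(1 / (d + 4)) * n^(-1 / (d + 4))
  list(z = z, y = y, h = h, center = mu, scale = sd_)
}

predict_nw <- function(fit, newdata) {
  z <- scale(newdata, center = fit$center, scale = fit$scale)
  d <- ncol(z)
  apply(z, 1L, function(q) {
    d2 <- colSums((t(fit$z) - q)^2) / d  # mean squared per-dim distance
    logw <- -d2 / (2 * fit$h^2)
    w <- exp(logw - max(logw))  # shift to avoid underflow
    sum(w * fit$y) / sum(w)
  })
}

#' Estimate intake amount
#'
#' Predicts grams for one or more 89-dimensional sip feature vectors.
#' Estimates are clipped below at a small positive epsilon (negative grams
#' are physically meaningless); clipped predictions are flagged in the
#' `"clipped"` attribute. Batch prediction equals element-wise prediction.
#'
#' @param estimator An `amount_estimator` from [train_estimator()].
#' @param x Numeric vector of length 89 or a matrix with 89 columns.
#' @param epsilon Lower clip bound in grams.
#' @return Numeric vector of estimated grams with a logical `"clipped"`
#'   attribute.
#' @export
estimate_amount <- function(estimator, x, epsilon = 1e-6) {
  stopifnot(inherits(estimator, "amount_estimator"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != estimator$p) {
    stop("feature vector has ", ncol(x), " values; estimator expects ",
         estimator$p, call. = FALSE)
  }
  colnames(x) <- estimator$features
  pred <- switch(estimator$spec$model_name,
    linear = {
      suppressWarnings(unname(stats::predict(estimator$fit,
                                             data.frame(x))))
    },
    gaussian_kernel = predict_nw(estimator$fit, x),
    unname(stats::predict(estimator$fit, x))
  )
  clipped <- pred < epsilon
  pred[clipped] <- epsilon
  attr(pred, "clipped") <- clipped
  pred
}

#' @export
print.amount_estimator <- function(x, ...) {
  sc <- if (x$spec$scope == "dependent") {
    paste0("dependent (", x$spec$container, ")")
  } else "independent"
  cat(sprintf("<amount_estimator> %s, %s scope, %d features\n",
              x$spec$model_name, sc, x$p))
  invisible(x)
}
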