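# Generalized regression neural network (Nadaraya-Watson kernel regression).
#
# A one-pass lazy learner: training stores the standardised inputs X_i and
# targets Y_i; prediction is the kernel-weighted average
#   Yhat(x) = sum_i Y_i exp(-D_i^2 / (2 sigma^2)) / sum_i exp(-D_i^2 / (2 sigma^2))
# with D_i^2 the squared Euclidean distance to the i-th stored input and a
# single bandwidth sigma.  Exponents are stabilised by subtracting the row
# maximum before exponentiation, so at least one kernel weight is exactly 1
# and the weights can never all underflow.

#' Fit a GRNN model
#'
#' @param X Numeric matrix of (standardised) training inputs.
#' @param y Numeric vector of training targets, one per row of `X`.
#' @param sigma Kernel bandwidth, > 0, in standardised-input units.
#' @return Object of class `grnn`.
#' @export
grnn_fit <- function(X, y, sigma) {
  X <- as_num_matrix(X, "X")
  if (length(sigma) != 1 || !is.finite(sigma) || sigma <= 0) {
    stopf("`sigma` must be a single positive number")
  }
  if (nrow(X) < 1 || nrow(X) != length(y)) {
    stopf("`X` and `y` must have matching, non-zero length")
  }
  structure(list(X = X, y = as.numeric(y), sigma = sigma), class = "grnn")
}

#' Predict from a GRNN model
#'
#' Predictions are convex combinations of the stored targets and therefore
#' always lie within their range.
#'
#' @param object A [grnn_fit()] model.
#' @param newdata Numeric matrix of query points (columns as in training).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.grnn <- function(object, newdata, ...) {
  newdata <- as_num_matrix(newdata, "newdata")
  if (ncol(newdata) != ncol(object$X)) {
    stopf("`newdata` has %d columns, model expects %d",
          ncol(newdata), ncol(object$X))
  }
  loge <- -sqdist(newdata, object$X) / (2 * object$sigma^2)
  w <- exp(loge - apply(loge, 1, max))
  as.numeric((w %*% object$y) / rowSums(w))
}

#' Default bandwidth grid
#'
#' Log-spaced candidates in standardised-input units.
#'
#' @param n Number of candidates.
#' @param range Lower/upper bandwidth bounds.
#' @return Numeric vector.
#' @export
grnn_bandwidth_grid <- function(n = 20, range = c(0.05, 3)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Select the GRNN bandwidth by cross-validation
#'
#' Picks the grid value minimising mean validation RMSE over the supplied
#' folds; exact ties are broken towards the larger (smoother) bandwidth.
#'
#' @param X,y Training data.
#' @param grid Positive bandwidth candidates.
#' @param folds List of validation index vectors (row indices into `X`).
#' @return List with `sigma` (the winner) and `scores` (per-candidate mean
#'   RMSE).
#' @export
grnn_select_bandwidth <- function(X, y, grid = grnn_bandwidth_grid(), folds) {
  stopifnot(length(grid) > 0, all(grid > 0))
  X <- as_num_matrix(X, "X")
  scores <- vapply(grid, function(s) {
    errs <- vapply(folds, function(va) {
      fit <- grnn_fit(X[-va, , drop = FALSE], y[-va], s)
      rmse(y[va], predict(fit, X[va, , drop = FALSE]))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  tied <- which(scores <= min(scores) + 1e-12 * max(1, min(scores)))
  list(sigma = max(grid[tied]), scores = scores)
}
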