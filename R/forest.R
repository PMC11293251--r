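# Random forest regression, backed by the randomForest package.
#
# Each of K trees is grown on an n-sample bootstrap of the training data;
# the ensemble prediction is the arithmetic mean of the K tree predictions,
# and the out-of-bag (OOB) samples of each tree provide an internal error
# estimate.

#' Fit a random forest surrogate
#'
#' @param X Numeric matrix of training inputs.
#' @param y Numeric vector of training targets.
#' @param ntree Number of trees.
#' @param mtry Features tried per split, `1 <= mtry <= ncol(X)`.
#' @param node_size Minimum terminal node size.
#' @param seed Optional seed (bootstrap and split sampling).
#' @return Object of class `rf_surrogate` wrapping the fitted forest.
#' @export
rf_fit <- function(X, y, ntree = 500, mtry = max(1, floor(ncol(X) / 3)),
                   node_size = 5, seed = NULL) {
  X <- as_num_matrix(X, "X")
  stopifnot(length(y) == nrow(X))
  if (ntree < 1) stopf("`ntree` must be >= 1")
  if (mtry < 1 || mtry > ncol(X)) {
    stopf("`mtry` must be in [1, %d]", ncol(X))
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- randomForest::randomForest(
    x = X, y = as.numeric(y), ntree = ntree, mtry = mtry,
    nodesize = node_size, keep.inbag = TRUE, keep.forest = TRUE)
  structure(list(fit = fit, y = as.numeric(y), ntree = ntree, mtry = mtry,
                 node_size = node_size),
            class = "rf_surrogate")
}

#' Predict from a random forest surrogate
#'
#' @param object An [rf_fit()] model.
#' @param newdata Numeric matrix of query points.
#' @param all_trees If `TRUE`, also return the per-tree predictions.
#' @param ... Unused.
#' @return Numeric vector, or (with `all_trees`) a list with `aggregate`
#'   and the `individual` tree prediction matrix.
#' @export
predict.rf_surrogate <- function(object, newdata, all_trees = FALSE, ...) {
  newdata <- as_num_matrix(newdata, "newdata")
  if (all_trees) {
    p <- predict(object$fit, newdata, predict.all = TRUE)
    list(aggregate = as.numeric(p$aggregate), individual = p$individual)
  } else {
    as.numeric(predict(object$fit, newdata))
  }
}

#' Out-of-bag RMSE of a random forest surrogate
#'
#' Uses, for every training sample, only the trees whose bootstrap excluded
#' it.  Samples that ended up in every bootstrap (possible at very small
#' `ntree`) are excluded from the error with a message.
#'
#' @param model An [rf_fit()] model.
#' @return OOB root mean square error.
#' @export
rf_oob_error <- function(model) {
  stopifnot(inherits(model, "rf_surrogate"))
  pred <- model$fit$predicted
  miss <- !is.finite(pred)
  if (any(miss)) {
    message(sprintf("%d sample(s) were in-bag for every tree; excluded from OOB error",
                    sum(miss)))
  }
  rmse(model$y[!miss], pred[!miss])
}

#' Per-tree out-of-bag fractions
#'
#' Fraction of training samples left out of each tree's bootstrap; for an
#' n-sample bootstrap the expectation is (1 - 1/n)^n, about 0.368.
#'
#' @param model An [rf_fit()] model.
#' @return Numeric vector, one fraction per tree.
#' @export
rf_oob_fraction <- function(model) {
  stopifnot(inherits(model, "rf_surrogate"))
  colMeans(model$fit$inbag == 0)
}
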