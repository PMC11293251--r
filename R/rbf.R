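# Radial basis function network regression.
#
# One hidden layer of Gaussian units phi_i(x) = exp(-||x - c_i||^2 / (2 s^2))
# and a linear output layer Yhat = sum_i phi_i(x) w_i (no bias term).
# Centers come from k-means on the (standardised) inputs, a common width is
# the median pairwise center distance, and the output weights solve a
# ridge-regularised least-squares problem via an augmented QR factorisation
# (which avoids squaring the condition number of the design).

rbf_design <- function(X, centers, width) {
  exp(-sqdist(X, centers) / (2 * width^2))
}

#' Fit an RBF network
#'
#' With `n_centers` equal to the number of (distinct) training rows the
#' design is square and, for small ridge penalties, the network
#' interpolates the training targets.
#'
#' @param X Numeric matrix of (standardised) training inputs.
#' @param y Numeric vector of training targets.
#' @param n_centers Number of hidden units, `1 <= n_centers <= nrow(X)`.
#'   Capped at the number of distinct input rows (k-means cannot place more
#'   centers than that).
#' @param ridge Ridge penalty on the output weights.
#' @param seed Optional seed for the k-means center placement.
#' @return Object of class `rbf_net` with `centers`, `width`, `weights`.
#' @export
rbf_fit <- function(X, y, n_centers, ridge = 1e-8, seed = NULL) {
  X <- as_num_matrix(X, "X")
  stopifnot(length(y) == nrow(X))
  if (n_centers < 1 || n_centers > nrow(X)) {
    stopf("`n_centers` must be in [1, %d]", nrow(X))
  }
  ux <- unique(X)
  if (n_centers >= nrow(ux)) {
    centers <- ux
  } else {
    if (!is.null(seed)) set.seed(seed)
    centers <- kmeans(ux, centers = n_centers, nstart = 5,
                      iter.max = 100)$centers
  }
  width <- if (nrow(centers) > 1) {
    # median nearest-neighbour distance gives cluster-spacing-scale widths;
    # capping at twice the *minimum* NN distance keeps the design matrix
    # well-conditioned (and the square all-centers case an interpolant)
    # even when two centers lie very close together
    d2 <- sqdist(centers, centers)
    diag(d2) <- Inf
    nn <- sqrt(apply(d2, 1, min))
    min(stats::median(nn), 2 * min(nn))
  } else {
    1.0
  }
  if (!is.finite(width) || width <= 0) width <- 1.0
  Phi <- rbf_design(X, centers, width)
  # ridge LS through QR of the lambda-augmented system
  aug <- rbind(Phi, sqrt(ridge) * diag(ncol(Phi)))
  rhs <- c(y, numeric(ncol(Phi)))
  w <- qr.coef(qr(aug), rhs)
  w[is.na(w)] <- 0
  structure(list(centers = centers, width = width, weights = as.numeric(w),
                 ridge = ridge),
            class = "rbf_net")
}

#' Predict from an RBF network
#'
#' @param object An [rbf_fit()] model.
#' @param newdata Numeric matrix of query points.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rbf_net <- function(object, newdata, ...) {
  newdata <- as_num_matrix(newdata, "newdata")
  if (ncol(newdata) != ncol(object$centers)) {
    stopf("`newdata` has %d columns, model expects %d",
          ncol(newdata), ncol(object$centers))
  }
  as.numeric(rbf_design(newdata, object$centers, object$width) %*%
               object$weights)
}
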