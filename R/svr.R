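# Epsilon-insensitive support vector regression with a Gaussian kernel,
# backed by the libsvm solver in e1071.
#
# The fitted model exposes the dual coefficients beta_i = a_i - a_i* (one
# per training point, zero off the support set), which must satisfy the
# equality constraint sum(beta) = 0 and the box constraints |beta_i| <= C,
# and the KKT conditions relating beta_i to the position of the residual
# relative to the epsilon tube.

#' Fit an epsilon-SVR surrogate
#'
#' @param X Numeric matrix of (standardised) training inputs.
#' @param y Numeric vector of training targets.
#' @param C Regularisation constant, > 0.
#' @param epsilon Half-width of the insensitive tube, >= 0.
#' @param gamma Gaussian kernel parameter `exp(-gamma * ||x - x'||^2)`.
#' @param tol Solver termination tolerance.
#' @return Object of class `svr_surrogate` with the full-length dual
#'   coefficient vector `dual_coefs`, bias `b` and the wrapped libsvm fit.
#' @export
svr_fit <- function(X, y, C = 1, epsilon = 0.1, gamma = 1 / ncol(X),
                    tol = 1e-3) {
  X <- as_num_matrix(X, "X")
  stopifnot(length(y) == nrow(X))
  if (C <= 0) stopf("`C` must be > 0")
  if (epsilon < 0) stopf("`epsilon` must be >= 0")
  fit <- e1071::svm(x = X, y = as.numeric(y), type = "eps-regression",
                    kernel = "radial", cost = C, epsilon = epsilon,
                    gamma = gamma, tolerance = tol, scale = FALSE,
                    fitted = FALSE)
  beta <- numeric(nrow(X))
  support <- if (fit$tot.nSV > 0) as.integer(fit$index) else integer(0)
  if (length(support)) beta[support] <- as.numeric(fit$coefs)
  structure(list(fit = fit, X = X, y = as.numeric(y), C = C,
                 epsilon = epsilon, gamma = gamma, tol = tol,
                 dual_coefs = beta, b = -fit$rho,
                 support = support),
            class = "svr_surrogate")
}

#' Predict from an SVR surrogate
#'
#' @param object An [svr_fit()] model.
#' @param newdata Numeric matrix of query points.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.svr_surrogate <- function(object, newdata, ...) {
  newdata <- as_num_matrix(newdata, "newdata")
  if (length(object$support) == 0) {
    # all dual coefficients are zero (target fit entirely inside the tube):
    # the predictor is the constant bias
    return(rep(object$b, nrow(newdata)))
  }
  as.numeric(predict(object$fit, newdata))
}

#' KKT residual of a fitted SVR model
#'
#' Maximum violation over: the equality constraint `|sum(beta)|`, the box
#' constraints `|beta_i| <= C`, and the complementarity conditions --
#' zero-coefficient points must lie inside the (tol-widened) tube, free
#' support vectors on its boundary, and bound support vectors on or outside
#' it.
#'
#' @param model An [svr_fit()] model.
#' @return Single non-negative number (0 = exactly feasible/complementary).
#' @export
svr_kkt_residual <- function(model) {
  stopifnot(inherits(model, "svr_surrogate"))
  beta <- model$dual_coefs
  C <- model$C
  eps <- model$epsilon
  r <- abs(predict(model, model$X) - model$y)
  at_zero <- beta == 0
  at_bound <- abs(abs(beta) - C) <= model$tol & !at_zero
  free <- !at_zero & !at_bound
  viol <- c(abs(sum(beta)),
            max(0, max(abs(beta)) - C),
            if (any(at_zero)) pmax(0, r[at_zero] - eps) else 0,
            if (any(free)) abs(r[free] - eps) else 0,
            if (any(at_bound)) pmax(0, eps - r[at_bound]) else 0)
  max(viol)
}
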