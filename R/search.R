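# Common fit/predict surface over the four surrogate families and
# cross-validated hyperparameter search.

surrogate_families <- c("grnn", "rbf", "rf", "svr")

#' Fit a surrogate model of a given family
#'
#' Thin dispatcher used by the search and pipeline code; `params` holds the
#' family's hyperparameters (see the family fit functions for names).
#'
#' @param family One of `"grnn"`, `"rbf"`, `"rf"`, `"svr"`.
#' @param X,y Training data (standardised inputs/targets).
#' @param params Named list of hyperparameters.
#' @param seed Optional seed for stochastic fitters (rf, rbf k-means).
#' @return A fitted model with a `predict` method.
#' @export
surrogate_fit <- function(family, X, y, params = list(), seed = NULL) {
  family <- match.arg(family, surrogate_families)
  switch(family,
    grnn = grnn_fit(X, y, sigma = params$sigma %||% 0.5),
    rbf = rbf_fit(X, y,
                  n_centers = min(params$n_centers %||% nrow(as_num_matrix(X)),
                                  nrow(as_num_matrix(X))),
                  ridge = params$ridge %||% 1e-8, seed = seed),
    rf = rf_fit(X, y, ntree = params$ntree %||% 500,
                mtry = params$mtry %||% max(1, floor(ncol(as_num_matrix(X)) / 3)),
                node_size = params$node_size %||% 5, seed = seed),
    svr = svr_fit(X, y, C = params$C %||% 1,
                  epsilon = params$epsilon %||% 0.1,
                  gamma = params$gamma %||% 1 / ncol(as_num_matrix(X)),
                  tol = params$tol %||% 1e-3)
  )
}

#' Default hyperparameter search spaces
#'
#' Grids on standardised data: 20 log-spaced GRNN bandwidths in \[0.05, 3\];
#' RBF hidden-layer sizes (ridge fixed at 1e-8); random forest `mtry` and
#' node sizes at `ntree` 500; the usual C/epsilon/gamma grid for SVR.
#'
#' @param family Surrogate family name.
#' @param p Number of input columns (used for rf defaults).
#' @return A `data.frame`, one row per candidate configuration.
#' @export
default_search_space <- function(family, p = 6) {
  family <- match.arg(family, surrogate_families)
  switch(family,
    grnn = data.frame(sigma = grnn_bandwidth_grid()),
    rbf = expand.grid(n_centers = c(8, 16, 32, 64), ridge = 1e-8),
    rf = expand.grid(ntree = 500, mtry = unique(pmin(c(1, 2, 4, p), p)),
                     node_size = c(2, 5)),
    svr = expand.grid(C = c(0.1, 1, 10, 100), epsilon = c(0.01, 0.05, 0.1),
                      gamma = c(0.05, 0.1, 0.5, 1))
  )
}

#' Cross-validated hyperparameter search
#'
#' Exhaustive over the candidate grid when it has at most `max_eval` rows,
#' otherwise a seeded random subsample of `max_eval` candidates.  The winner
#' minimises mean validation RMSE across folds; exact ties are resolved by
#' the lexicographic order of the candidate's parameter values, so the
#' result does not depend on grid ordering.
#'
#' @param family Surrogate family name.
#' @param X,y Training data.
#' @param space `data.frame` of candidate configurations (one per row).
#' @param folds List of validation index vectors into `X`.
#' @param seed Seed used for subsampling and stochastic fits.
#' @param max_eval Evaluation budget for large spaces.
#' @return List with `best` (named list of winning parameters), `score`
#'   (its mean CV RMSE) and `scores` (the evaluated grid with scores).
#' @export
hyperparameter_search <- function(family, X, y, space = NULL, folds,
                                  seed = NULL, max_eval = 200) {
  X <- as_num_matrix(X, "X")
  if (is.null(space)) space <- default_search_space(family, ncol(X))
  if (!is.data.frame(space) || nrow(space) == 0) {
    stopf("`space` must be a non-empty data.frame of configurations")
  }
  if (nrow(space) > max_eval) {
    if (!is.null(seed)) set.seed(seed)
    space <- space[sample.int(nrow(space), max_eval), , drop = FALSE]
  }
  errors <- character(0)
  scores <- vapply(seq_len(nrow(space)), function(i) {
    params <- as.list(space[i, , drop = FALSE])
    fold_err <- vapply(folds, function(va) {
      tryCatch({
        fit <- surrogate_fit(family, X[-va, , drop = FALSE], y[-va], params,
                             seed = seed)
        rmse(y[va], predict(fit, X[va, , drop = FALSE]))
      }, error = function(e) {
        errors <<- c(errors, conditionMessage(e))
        Inf
      })
    }, numeric(1))
    mean(fold_err)
  }, numeric(1))
  if (all(!is.finite(scores))) {
    stopf("all %d configurations failed to fit; causes: %s",
          nrow(space), paste(unique(errors), collapse = "; "))
  }
  tied <- which(scores == min(scores))
  if (length(tied) > 1) {
    ord <- do.call(order, as.list(space[tied, , drop = FALSE]))
    best_i <- tied[ord[1]]
  } else {
    best_i <- tied
  }
  list(best = as.list(space[best_i, , drop = FALSE]),
       score = scores[best_i],
       scores = cbind(space, cv_rmse = scores))
}
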