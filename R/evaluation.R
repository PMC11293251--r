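# k-fold cross-validation and the model-comparison table / best-family
# selection.

#' Cross-validate a surrogate family on the training rows of a split plan
#'
#' For each fold, hyperparameters are chosen by a nested search on the
#' remaining folds, a model is fitted on those folds and scored (R2, RMSE,
#' MBE) on the held-out fold.  A final search over all folds then picks the
#' winning configuration, and the returned model is refitted on every
#' training row with it.
#'
#' @param family Surrogate family name.
#' @param X,y Full data matrices (standardised); only rows in `plan$train`
#'   are used.
#' @param plan A [make_split()] plan.
#' @param space Optional candidate grid (defaults per family).
#' @param seed Optional seed for stochastic fits / subsampling.
#' @return List with `fold_metrics` (per-fold R2/RMSE/MBE), `cv_rmse`
#'   (their mean RMSE), `best` (winning hyperparameters), and `model`
#'   (refitted on all training rows).
#' @export
cross_validate <- function(family, X, y, plan, space = NULL, seed = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  X <- as_num_matrix(X, "X")
  folds <- split_folds(plan)
  fold_metrics <- t(vapply(seq_along(folds), function(f) {
    va <- folds[[f]]
    tr <- setdiff(plan$train, va)
    inner <- lapply(folds[-f], function(idx) match(idx, tr))
    sr <- tryCatch(
      hyperparameter_search(family, X[tr, , drop = FALSE], y[tr],
                            space = space, folds = inner, seed = seed),
      error = function(e) stopf("fold %d: %s", f, conditionMessage(e)))
    fit <- surrogate_fit(family, X[tr, , drop = FALSE], y[tr], sr$best,
                         seed = seed)
    metric_row(y[va], predict(fit, X[va, , drop = FALSE]))
  }, c(R2 = 0, RMSE = 0, MBE = 0)))
  final <- hyperparameter_search(
    family, X[plan$train, , drop = FALSE], y[plan$train], space = space,
    folds = lapply(folds, function(idx) match(idx, plan$train)), seed = seed)
  model <- surrogate_fit(family, X[plan$train, , drop = FALSE],
                         y[plan$train], final$best, seed = seed)
  list(fold_metrics = as.data.frame(fold_metrics),
       cv_rmse = mean(fold_metrics[, "RMSE"]),
       best = final$best, model = model)
}

#' Compare surrogate families and select the best
#'
#' Families are ranked by mean test-set R2 across the seven traits
#' (original units); ties closer than 1e-6 are broken by the lower mean
#' test RMSE on standardised targets.  All reports must have been computed
#' on the identical split plan.
#'
#' @param reports Named list of family reports as produced by the pipeline
#'   (each with elements `family`, `metrics` and `plan`).
#' @return List with `best` (family name), `ranking` (data.frame) and
#'   `table` (the full metric grid, long format).
#' @export
compare_models <- function(reports) {
  if (length(reports) < 2) stopf("need at least 2 family reports to compare")
  plans <- lapply(reports, `[[`, "plan")
  for (i in seq_along(plans)[-1]) {
    if (!identical(unclass(plans[[1]]), unclass(plans[[i]]))) {
      stopf("family reports were computed on different splits; comparison invalid")
    }
  }
  table <- do.call(rbind, lapply(reports, `[[`, "metrics"))
  rownames(table) <- NULL
  stat <- function(df, metric, scale) {
    sel <- df$subset == "testing" & df$metric == metric & df$scale == scale
    mean(df$value[sel])
  }
  ranking <- do.call(rbind, lapply(reports, function(rep) {
    data.frame(family = rep$family,
               mean_test_r2 = stat(rep$metrics, "R2", "original"),
               mean_test_rmse_std = stat(rep$metrics, "RMSE", "standardized"))
  }))
  rownames(ranking) <- NULL
  # primary key: R2 rounded at the tie tolerance; secondary: standardized RMSE
  key <- round(ranking$mean_test_r2 / 1e-6) * 1e-6
  ord <- order(-key, ranking$mean_test_rmse_std, ranking$family)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  list(best = ranking$family[1], ranking = ranking, table = table)
}
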