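# A fitted per-trait model bundle of one family, together with the
# normalisation used, and its coupling to the optimizer.

#' Bundle per-trait surrogate models of one family
#'
#' @param cultivar Cultivar label.
#' @param family Surrogate family name.
#' @param models Named list of seven fitted models (one per trait, in
#'   [trait_names()] order), trained on standardised inputs/targets.
#' @param x_params,y_params The [zscore_fit()] parameters of the inputs and
#'   targets (shared across traits).
#' @param hyperparams Named list of the chosen hyperparameters per trait.
#' @return Object of class `surrogate_set`.
#' @export
surrogate_set <- function(cultivar, family, models, x_params, y_params,
                          hyperparams = NULL) {
  if (!setequal(names(models), trait_names())) {
    stopf("`models` must contain exactly one model per trait")
  }
  structure(list(cultivar = cultivar, family = family,
                 models = models[trait_names()],
                 x_params = x_params, y_params = y_params,
                 hyperparams = hyperparams),
            class = "surrogate_set")
}

#' Predict all seven traits at treatment conditions
#'
#' Encodes the decisions (one-hot stress), standardises with the stored
#' training parameters, predicts each trait and returns original-scale
#' values.
#'
#' @param object A [surrogate_set()].
#' @param newdata `data.frame` with columns `gaba`, `dpt`, `stress` (or the
#'   dataset-style names `gaba_mM`, `dpt_days`).
#' @param ... Unused.
#' @return n x 7 matrix of trait predictions in original units.
#' @export
predict.surrogate_set <- function(object, newdata, ...) {
  g <- newdata$gaba %||% newdata$gaba_mM
  t <- newdata$dpt %||% newdata$dpt_days
  s <- newdata$stress
  if (is.null(g) || is.null(t) || is.null(s)) {
    stopf("`newdata` needs gaba, dpt and stress columns")
  }
  onehot <- vapply(stress_levels(), function(lv) as.numeric(s == lv),
                   numeric(length(g)))
  if (length(g) == 1) onehot <- matrix(onehot, nrow = 1)
  colnames(onehot) <- paste0("stress_", stress_levels())
  X <- cbind(gaba_mM = g, dpt_days = t, onehot)
  Xs <- zscore_apply(X, object$x_params)
  Ys <- vapply(trait_names(), function(tr) {
    predict(object$models[[tr]], Xs)
  }, numeric(length(g)))
  if (length(g) == 1) Ys <- matrix(Ys, nrow = 1, dimnames = list(NULL, trait_names()))
  zscore_invert(Ys, object$y_params)
}

#' Build the NSGA-II objective function from a surrogate set
#'
#' The returned function maps decision data.frames to the 7-column
#' objective matrix in original trait units.  Out-of-bounds decisions are
#' clipped to the bounds; the number of clipped values is kept on the
#' function's `clip_count` attribute (an environment counter).
#'
#' @param set A [surrogate_set()].
#' @param gaba_bounds,dpt_bounds Decision bounds used for clipping.
#' @return Function `f(decisions) -> matrix`; `attr(f, "clips")()` reports
#'   how many coordinates were clipped so far.
#' @export
make_objective <- function(set, gaba_bounds = c(0, 40),
                           dpt_bounds = c(14, 45)) {
  stopifnot(inherits(set, "surrogate_set"))
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  f <- function(decisions) {
    g <- decisions$gaba %||% decisions$gaba_mM
    t <- decisions$dpt %||% decisions$dpt_days
    gc <- clip(g, gaba_bounds)
    tc <- clip(t, dpt_bounds)
    n_clip <- sum(gc != g) + sum(tc != t)
    if (n_clip > 0) counter$n <- counter$n + n_clip
    predict(set, data.frame(gaba = gc, dpt = tc,
                            stress = decisions$stress,
                            stringsAsFactors = FALSE))
  }
  attr(f, "clips") <- function() counter$n
  f
}
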