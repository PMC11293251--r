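# Model accuracy metrics: coefficient of determination, root mean square
# error and mean bias error.

#' Coefficient of determination
#'
#' `1 - sum((est - obs)^2) / sum((obs - mean(obs))^2)`; can be negative for
#' fits worse than the observed mean.
#'
#' @param obs Observed values (non-constant, length >= 2).
#' @param est Estimated values of the same length.
#' @return Single number, at most 1.
#' @export
r_squared <- function(obs, est) {
  if (length(obs) != length(est) || length(obs) < 2) {
    stopf("`obs` and `est` must have equal length >= 2")
  }
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stopf("`obs` is constant; R^2 is undefined")
  1 - sum((est - obs)^2) / ss_tot
}

#' Root mean square error
#'
#' @param obs,est Equal-length numeric vectors.
#' @return Non-negative number.
#' @export
rmse <- function(obs, est) {
  stopifnot(length(obs) == length(est), length(obs) >= 1)
  sqrt(mean((est - obs)^2))
}

#' Mean bias error
#'
#' Sign convention: positive values mean over-estimation (`est - obs`).
#'
#' @param obs,est Equal-length numeric vectors.
#' @return Single number.
#' @export
mbe <- function(obs, est) {
  stopifnot(length(obs) == length(est), length(obs) >= 1)
  mean(est - obs)
}

metric_row <- function(obs, est) {
  c(R2 = r_squared(obs, est), RMSE = rmse(obs, est), MBE = mbe(obs, est))
}
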