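# Internal helpers shared across modules.

#' Trait names in canonical order
#'
#' Seven physio-biochemical traits: soluble protein (mg/g FW), ascorbate
#' peroxidase, superoxide dismutase, peroxidase and catalase activities
#' (U/mg FW), malondialdehyde (umol/g FW) and hydrogen peroxide (mg/g FW).
#'
#' @return Character vector of length 7.
#' @export
trait_names <- function() {
  c("protein", "APX", "SOD", "POD", "CAT", "MDA", "H2O2")
}

#' Stress categories in canonical order
#'
#' Control (C), drought (D), salinity (S) and combined drought-salinity
#' (DxS).
#'
#' @return Character vector of length 4.
#' @export
stress_levels <- function() {
  c("C", "D", "S", "DxS")
}

#' Objective senses of the seven traits
#'
#' Antioxidant enzymes and protein are maximised; the oxidative-damage
#' markers MDA and H2O2 are minimised.
#'
#' @return Named character vector (`"max"` or `"min"`) over [trait_names()].
#' @export
trait_senses <- function() {
  c(protein = "max", APX = "max", SOD = "max", POD = "max", CAT = "max",
    MDA = "min", H2O2 = "min")
}

# Deterministic sub-seed from a global seed and a stage tag, kept < 2^31.
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Squared Euclidean distances between rows of A and rows of B.
sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  pmax(d, 0)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(...) stop(sprintf(...), call. = FALSE)

as_num_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (!is.matrix(x) || !is.numeric(x)) {
    stopf("`%s` must be a numeric matrix", arg)
  }
  x
}
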