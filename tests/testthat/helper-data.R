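# Shared fixtures and independent oracles, built in code at test time.

# Random regression data with well-separated inputs (so kernel methods can
# be probed at extreme bandwidths without accidental near-duplicates).
random_regression_data <- function(n = 40, p = 3, noise = 0.1) {
  repeat {
    X <- matrix(rnorm(n * p), n, p)
    d2 <- gabaopt:::sqdist(X, X)
    diag(d2) <- Inf
    if (min(d2) > 1e-3) break
  }
  y <- sin(X[, 1]) + 0.5 * X[, 2]^2 + rnorm(n, 0, noise)
  list(X = X, y = y)
}

# Simple deterministic validation folds over 1..n.
simple_folds <- function(n, k = 4) {
  split(seq_len(n), rep_len(seq_len(k), n))
}

# Brute-force non-dominated sorting oracle: repeatedly peel the set of
# individuals not dominated by any remaining individual, using dominates().
brute_force_fronts <- function(obj, senses) {
  remaining <- seq_len(nrow(obj))
  fronts <- list()
  while (length(remaining)) {
    nd <- vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        j != i && dominates(obj[j, ], obj[i, ], senses)
      }, logical(1)))
    }, logical(1))
    fronts[[length(fronts) + 1]] <- remaining[nd]
    remaining <- remaining[!nd]
  }
  fronts
}

# A random synthetic configuration with valid orderings and a shared
# interior optimum, for true_optimum() grid checks.
random_config <- function(seed) {
  set.seed(seed)
  g_opt <- runif(1, 2, 38)
  t_peak <- runif(1, 16, 43)
  surfaces <- default_surfaces("Atabaki", gaba_opt = g_opt,
                               time_peak = t_peak)
  # perturb amplitudes/widths while keeping the invariants
  for (tr in names(surfaces)) {
    sf <- surfaces[[tr]]
    if (sf$sense == "max") {
      sf$amplitude <- sf$amplitude * runif(1, 0.5, 1.5)
      sf$gaba_width <- runif(1, 5, 15)
      sf$time_width_left <- runif(1, 4, 10)
      sf$time_width_right <- runif(1, 8, 16)
    }
    surfaces[[tr]] <- sf
  }
  synthetic_config(surfaces = surfaces, seed = seed)
}
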