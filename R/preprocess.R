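# Encoding, z-score standardisation and data partitioning.

#' Encode a stress dataset into numeric design and target matrices
#'
#' GABA dose and days post-treatment pass through as numeric columns; the
#' stress category expands to four one-hot indicators in the fixed order
#' C, D, S, DxS.  Targets are copied in the fixed trait order.
#'
#' @param dataset A `stress_dataset` (see [generate_dataset()]).
#' @return List of class `encoded_matrix` with elements `X` (n x 6 input
#'   matrix), `Y` (n x 7 target matrix) and `cultivar`.
#' @export
encode_inputs <- function(dataset) {
  stopifnot(is.data.frame(dataset))
  bad <- which(!dataset$stress %in% stress_levels())
  if (length(bad)) {
    stopf("unknown stress category '%s' in row %d",
          dataset$stress[bad[1]], bad[1])
  }
  onehot <- vapply(stress_levels(),
                   function(s) as.numeric(dataset$stress == s),
                   numeric(nrow(dataset)))
  colnames(onehot) <- paste0("stress_", stress_levels())
  X <- cbind(gaba_mM = dataset$gaba_mM, dpt_days = dataset$dpt_days, onehot)
  Y <- as.matrix(dataset[, trait_names()])
  if (anyNA(X) || anyNA(Y)) stopf("dataset contains missing values")
  structure(list(X = X, Y = Y,
                 cultivar = unique(dataset$cultivar)),
            class = "encoded_matrix")
}

#' Recover stress labels from the one-hot block of an encoded matrix
#'
#' @param X Input matrix with the four `stress_*` indicator columns.
#' @return Character vector of stress labels.
#' @export
decode_stress <- function(X) {
  cols <- paste0("stress_", stress_levels())
  stopifnot(all(cols %in% colnames(X)))
  block <- X[, cols, drop = FALSE]
  if (any(abs(rowSums(block) - 1) > 1e-8)) {
    stopf("one-hot stress block must sum to 1 per row")
  }
  stress_levels()[max.col(block)]
}

#' Fit z-score standardisation parameters
#'
#' Column means and population standard deviations (divisor n).  Fit on
#' training rows only to avoid test-set leakage.
#'
#' @param m Numeric matrix (rows = samples).
#' @return List of class `zscore_params` with `mean`, `sd` and `columns`.
#' @export
zscore_fit <- function(m) {
  m <- as_num_matrix(m, "m")
  if (nrow(m) < 2) stopf("need at least 2 rows to standardise")
  mu <- colMeans(m)
  sigma <- sqrt(colMeans(sweep(m, 2, mu)^2))
  if (any(sigma <= 0)) {
    stopf("constant column(s) cannot be standardised: %s",
          paste(colnames(m)[sigma <= 0], collapse = ", "))
  }
  structure(list(mean = mu, sd = sigma, columns = colnames(m)),
            class = "zscore_params")
}

check_schema <- function(m, params) {
  if (!is.null(params$columns) && !is.null(colnames(m)) &&
      !identical(colnames(m), params$columns)) {
    stopf("column schema does not match standardisation parameters")
  }
  if (ncol(m) != length(params$mean)) {
    stopf("matrix has %d columns, parameters expect %d",
          ncol(m), length(params$mean))
  }
}

#' Apply or invert z-score standardisation
#'
#' @param m Numeric matrix matching the schema of `params`.
#' @param params A [zscore_fit()] result.
#' @return Matrix of the same shape.
#' @export
zscore_apply <- function(m, params) {
  m <- as_num_matrix(m, "m")
  check_schema(m, params)
  sweep(sweep(m, 2, params$mean), 2, params$sd, `/`)
}

#' @rdname zscore_apply
#' @export
zscore_invert <- function(m, params) {
  m <- as_num_matrix(m, "m")
  check_schema(m, params)
  sweep(sweep(m, 2, params$sd, `*`), 2, params$mean, `+`)
}

#' Train/test split with k-fold assignment over the training rows
#'
#' A seeded uniform permutation; the first `floor(train_frac * n)` permuted
#' rows form the training set, the remainder the test set.  Folds are
#' assigned round-robin over the shuffled training indices, so fold sizes
#' differ by at most one.
#'
#' @param n Number of samples.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed.
#' @param train_frac Training fraction, default 0.85.
#' @return List of class `split_plan` with `train`, `test`, `fold`
#'   (parallel to `train`), `k`, `n`, `seed`.
#' @export
make_split <- function(n, k = 5, seed = 1L, train_frac = 0.85) {
  if (n < k || k < 2) stopf("need n >= k >= 2 (got n = %d, k = %d)", n, k)
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- floor(train_frac * n)
  train <- perm[seq_len(n_train)]
  test <- if (n_train < n) perm[seq.int(n_train + 1, n)] else integer(0)
  fold <- rep_len(seq_len(k), n_train)
  structure(list(train = train, test = test, fold = fold,
                 k = as.integer(k), n = as.integer(n),
                 seed = as.integer(seed), train_frac = train_frac),
            class = "split_plan")
}

#' Validation-fold index sets of a split plan
#'
#' @param plan A [make_split()] result.
#' @return List of `k` integer vectors of absolute row indices (the
#'   validation rows of each fold); their union is `plan$train`.
#' @export
split_folds <- function(plan) {
  stopifnot(inherits(plan, "split_plan"))
  lapply(seq_len(plan$k), function(f) plan$train[plan$fold == f])
}

#' Serialise a split plan or standardisation parameters to JSON
#'
#' @param x A `split_plan` or `zscore_params` object.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
provenance_json <- function(x, path = NULL) {
  json <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
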