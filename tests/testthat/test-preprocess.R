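test_that("encoding passes numerics through and one-hots stress", {
  ds <- generate_dataset(synthetic_config(seed = 1))
  enc <- encode_inputs(ds)
  expect_equal(dim(enc$X), c(192, 6))
  expect_equal(dim(enc$Y), c(192, 7))
  expect_equal(colnames(enc$X),
               c("gaba_mM", "dpt_days", "stress_C", "stress_D", "stress_S",
                 "stress_DxS"))
  i <- which(ds$gaba_mM == 10 & ds$stress == "S" & ds$dpt_days == 30)[1]
  expect_equal(unname(enc$X[i, ]), c(10, 30, 0, 0, 1, 0))
  expect_true(all(rowSums(enc$X[, 3:6]) == 1))
  # one-hot block is a bijection back to the labels
  expect_identical(decode_stress(enc$X), ds$stress)

  bad <- ds
  bad$stress[17] <- "DS"
  expect_error(encode_inputs(bad), "row 17")
})

test_that("z-score parameters follow the population formulas", {
  m <- cbind(a = c(14, 30, 45), b = c(1, 2, 4))
  p <- zscore_fit(m)
  expect_equal(unname(p$mean["a"]), mean(c(14, 30, 45)))
  expect_equal(unname(p$sd["a"]),
               sqrt(sum((c(14, 30, 45) - mean(c(14, 30, 45)))^2) / 3))
  # an already-standardised column is a fixed point
  z <- (m[, 1] - p$mean["a"]) / p$sd["a"]
  p2 <- zscore_fit(cbind(a = z, b = m[, 2]))
  expect_equal(unname(p2$mean["a"]), 0)
  expect_equal(unname(p2$sd["a"]), 1)
  expect_error(zscore_fit(cbind(a = c(1, 1, 1), b = 1:3)), "constant")
  expect_error(zscore_fit(m[1, , drop = FALSE]), "2 rows")
})

test_that("standardisation applies, inverts and guards its schema", {
  set.seed(42)
  m <- matrix(rnorm(200, 5, 3), 50, 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  p <- zscore_fit(m)
  z <- zscore_apply(m, p)
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(sqrt(colMeans(sweep(z, 2, colMeans(z))^2))), rep(1, 4),
               tolerance = 1e-10)
  expect_lt(max(abs(zscore_invert(z, p) - m)), 1e-10)
  # x = mu maps to 0 and back
  mu_row <- matrix(p$mean, 1, dimnames = list(NULL, colnames(m)))
  expect_equal(unname(zscore_apply(mu_row, p)[1, ]), rep(0, 4))
  expect_equal(unname(zscore_invert(matrix(0, 1, 4,
    dimnames = list(NULL, colnames(m))), p)[1, ]), unname(p$mean))
  expect_error(zscore_apply(m[, 1:3], p), "schema|columns")
})

test_that("normalisation parameters never see the test rows", {
  ds <- generate_dataset(synthetic_config(seed = 5))
  enc <- encode_inputs(ds)
  plan <- make_split(nrow(enc$X), 5, seed = 3)
  p1 <- zscore_fit(enc$Y[plan$train, ])
  mutated <- enc$Y
  mutated[plan$test, ] <- mutated[plan$test, ] * 100
  p2 <- zscore_fit(mutated[plan$train, ])
  expect_identical(p1, p2)
})

test_that("split plans partition samples and folds partition the train set", {
  plan <- make_split(192, 5, seed = 11)
  expect_length(plan$train, 163)  # floor(0.85 * 192)
  expect_length(plan$test, 29)
  expect_setequal(c(plan$train, plan$test), 1:192)
  folds <- split_folds(plan)
  expect_setequal(unlist(folds), plan$train)
  sizes <- lengths(folds)
  expect_lte(diff(range(sizes)), 1)
  expect_identical(unclass(make_split(192, 5, seed = 11)), unclass(plan))
  expect_false(identical(make_split(192, 5, seed = 12)$train, plan$train))

  plan10 <- make_split(10, 5, seed = 1, train_frac = 1)
  expect_equal(unname(lengths(split_folds(plan10))), rep(2, 5))
  expect_error(make_split(4, 5), "n >= k")
})
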