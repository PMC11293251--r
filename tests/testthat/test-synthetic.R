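test_that("full factorial design yields one row per condition and replicate", {
  ds <- generate_dataset(synthetic_config(seed = 1))
  expect_equal(nrow(ds), 4 * 4 * 3 * 4)
  expect_false(anyNA(ds))
  expect_true(all(as.matrix(ds[, trait_names()]) > 0))
  # row count formula holds for arbitrary level sets
  cfg <- synthetic_config(gaba_levels = c(0, 5, 15), dpt_levels = c(10, 20),
                          stress_lv = c("C", "DxS"), n_replicates = 3,
                          seed = 2)
  expect_equal(nrow(generate_dataset(cfg)), 3 * 2 * 2 * 3)
})

test_that("generation is reproducible from the seed and noise-free at cv 0", {
  a <- generate_dataset(synthetic_config(seed = 7))
  b <- generate_dataset(synthetic_config(seed = 7))
  c <- generate_dataset(synthetic_config(seed = 8))
  expect_identical(a, b)
  expect_false(identical(a, c))

  nf <- generate_dataset(synthetic_config(noise_cv = 0, seed = 1))
  per_cond <- split(nf$APX, interaction(nf$gaba_mM, nf$stress, nf$dpt_days))
  expect_true(all(vapply(per_cond, function(v) diff(range(v)) == 0,
                         logical(1))))
})

test_that("noiseless surfaces honour sense-specific shape contracts", {
  sf <- default_surfaces("Atabaki")
  # oxidative markers are non-increasing in dose at fixed stress/time
  for (tr in c("MDA", "H2O2")) {
    v <- true_response(sf[[tr]], seq(0, 40, 0.5), "DxS", 30)
    expect_true(all(diff(v) <= 1e-12), label = tr)
    expect_gt(true_response(sf[[tr]], 0, "DxS", 30),
              true_response(sf[[tr]], 40, "DxS", 30))
  }
  # enzyme surfaces peak at the configured optimum
  grid_g <- seq(0, 40, 0.25)
  grid_t <- seq(14, 45, 0.25)
  for (tr in c("protein", "APX", "SOD", "POD", "CAT")) {
    peak <- true_response(sf[[tr]], 20, "DxS", 25)
    expect_true(all(true_response(sf[[tr]], grid_g, "DxS", 25) <= peak + 1e-12))
    expect_true(all(true_response(sf[[tr]], 20, "DxS", grid_t) <= peak + 1e-12))
  }
  # time asymmetry: late values above early ones for enzymes and MDA
  for (tr in c("protein", "APX", "SOD", "POD", "CAT", "MDA")) {
    expect_gt(true_response(sf[[tr]], 20, "DxS", 45),
              true_response(sf[[tr]], 20, "DxS", 14), label = tr)
  }
  # H2O2 decays monotonically with time
  vt <- true_response(sf$H2O2, 20, "DxS", seq(14, 45, 0.5))
  expect_true(all(diff(vt) <= 1e-12))
  expect_error(true_response(sf$APX, 10, "drought", 30), "unknown stress")
})

test_that("noiseless optima are calibrated to the reported treatment optima", {
  for (cu in c("Atabaki", "Rabab")) {
    opt <- true_optimum(synthetic_config(cultivar = cu))
    expect_equal(opt$gaba, 20)
    expect_equal(opt$dpt, 25)
    expect_equal(opt$stress, "DxS")
    target <- if (cu == "Atabaki") {
      c(protein = 0.80, APX = 50.63, SOD = 0.54, POD = 1.53, CAT = 4.42,
        MDA = 0.12, H2O2 = 0.44)
    } else {
      c(protein = 0.69, APX = 51.51, SOD = 0.53, POD = 1.72, CAT = 5.66,
        MDA = 0.15, H2O2 = 0.55)
    }
    expect_equal(opt$traits, target, tolerance = 1e-10)
  }
})

test_that("true_optimum matches a dense grid search for randomized configs", {
  for (seed in 1:20) {
    cfg <- random_config(seed)
    opt <- true_optimum(cfg)
    sf <- cfg$surfaces$APX
    gg <- seq(min(cfg$gaba_levels), max(cfg$gaba_levels), 0.05)
    tt <- seq(min(cfg$dpt_levels), max(cfg$dpt_levels), 0.05)
    # the surface is a product of univariate bumps, so the argmax can be
    # located per axis at the other coordinate's optimum
    g_hat <- gg[which.max(true_response(sf, gg, opt$stress, opt$dpt))]
    t_hat <- tt[which.max(true_response(sf, opt$gaba, opt$stress, tt))]
    expect_lte(abs(g_hat - opt$gaba), 0.05 + 1e-9)
    expect_lte(abs(t_hat - opt$dpt), 0.05 + 1e-9)
    s_hat <- cfg$stress_lv[which.max(
      true_response(sf, opt$gaba, cfg$stress_lv, opt$dpt))]
    expect_identical(s_hat, opt$stress)
  }
})

test_that("replicate noise has the configured magnitude and stress contrast", {
  cv_sum <- list(APX = 0, MDA = 0)
  dxs_beats_c <- TRUE
  for (seed in 1:10) {
    ds <- generate_dataset(synthetic_config(seed = seed))
    for (tr in c("APX", "MDA")) {
      agg <- tapply(ds[[tr]],
                    interaction(ds$gaba_mM, ds$stress, ds$dpt_days),
                    function(v) sd(v) / mean(v))
      cv_sum[[tr]] <- cv_sum[[tr]] + agg[order(names(agg))]
    }
    m <- tapply(ds$APX, interaction(ds$gaba_mM, ds$dpt_days, ds$stress), mean)
    cells <- expand.grid(g = unique(ds$gaba_mM), t = unique(ds$dpt_days))
    for (i in seq_len(nrow(cells))) {
      key_d <- paste(cells$g[i], cells$t[i], "DxS", sep = ".")
      key_c <- paste(cells$g[i], cells$t[i], "C", sep = ".")
      if (m[[key_d]] <= m[[key_c]]) dxs_beats_c <- FALSE
    }
  }
  # per-condition CV averaged over the 10 seeds (a single 4-replicate CV
  # estimate has sampling sd ~ 0.02, so individual draws can leave the band)
  for (tr in names(cv_sum)) {
    cv_mean <- cv_sum[[tr]] / 10
    expect_true(all(cv_mean > 0.01 & cv_mean < 0.12), label = tr)
  }
  expect_true(dxs_beats_c)
})

test_that("datasets round-trip through the CSV schema", {
  ds <- generate_dataset(synthetic_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_stress_dataset(ds, path)
  back <- read_stress_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(ds), tolerance = 1e-12)
  expect_identical(readLines(path, n = 1),
                   paste(c("cultivar", "gaba_mM", "stress", "dpt_days",
                           "replicate", trait_names()), collapse = ","))
  # malformed token is rejected with its row number
  bad <- ds
  bad$stress[5] <- "drought"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_stress_dataset(path), "row 5")
})

test_that("config invariants are enforced and heavy truncation warns", {
  expect_error(synthetic_config(gaba_levels = c(10, 5)), "increasing")
  expect_error(synthetic_config(n_replicates = 0), "replicates")
  expect_error(synthetic_config(noise_cv = -0.1), "noise_cv")
  expect_error(synthetic_config(stress_lv = c("C", "X")), "unknown")
  expect_warning(generate_dataset(synthetic_config(noise_cv = 1, seed = 1)),
                 "truncation")
})
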