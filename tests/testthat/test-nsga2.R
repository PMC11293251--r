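test_that("dominance follows the sense-aware definition", {
  s <- c(a = "max", b = "min")
  expect_false(dominates(c(1, 1), c(1, 1), s))
  expect_true(dominates(c(2, 0.5), c(1, 1), s))
  expect_true(dominates(c(1, 0.5), c(1, 1), s))
  # better in one, worse in another: incomparable both ways
  expect_false(dominates(c(2, 2), c(1, 1), s))
  expect_false(dominates(c(1, 1), c(2, 2), s))
})

test_that("fast sorting matches the brute-force peeling oracle", {
  # hand-checkable 6-point, 2-objective minimisation set
  obj <- rbind(c(1, 5), c(2, 3), c(3, 1), c(2.5, 2.5), c(4, 4), c(5, 5))
  senses <- c("min", "min")
  fronts <- fast_nondominated_sort(obj, senses)
  expect_equal(fronts, brute_force_fronts(obj, senses))
  expect_equal(fronts[[1]], c(1, 2, 3, 4))

  # identical vectors are mutually non-dominated: one front
  same <- matrix(1, 7, 3)
  expect_length(fast_nondominated_sort(same, rep("min", 3)), 1)

  # randomized agreement across mixed senses
  set.seed(22)
  senses7 <- trait_senses()
  for (i in 1:30) {
    n <- sample(5:40, 1)
    obj <- matrix(rnorm(n * 7), n, 7)
    expect_equal(fast_nondominated_sort(obj, senses7),
                 brute_force_fronts(obj, senses7))
  }
})

test_that("crowding distance follows the neighbour-gap formula", {
  expect_equal(crowding_distance(matrix(rnorm(4), 2, 2)), c(Inf, Inf))
  tri <- rbind(c(0, 2), c(1, 1), c(2, 0))
  d <- crowding_distance(tri)
  expect_equal(d, c(Inf, 2, Inf))  # middle: (2-0)/2 per objective
  # min-max normalisation makes distances scale-invariant
  set.seed(23)
  obj <- matrix(rnorm(40), 10, 4)
  scaled <- obj
  scaled[, 2] <- scaled[, 2] * 1000
  expect_equal(crowding_distance(obj), crowding_distance(scaled))
  # a constant objective contributes nothing
  const <- cbind(c(0, 1, 2), 5)
  expect_equal(crowding_distance(const), c(Inf, 1, Inf))
})

test_that("ideal-point selection minimises the normalised utopia distance", {
  senses <- c("max", "min")
  expect_equal(select_ideal_point(matrix(c(3, 1), 1), senses), 1L)
  # a member best in everything wins with distance zero
  front <- rbind(c(5, 0.1), c(4, 0.5), c(3, 0.2))
  expect_equal(select_ideal_point(front, senses), 1L)
  # three-member hand computation
  front3 <- rbind(c(10, 4), c(8, 2), c(6, 1))
  nrm <- cbind((10 - front3[, 1]) / 4, (front3[, 2] - 1) / 3)
  expect_equal(select_ideal_point(front3, senses),
               which.min(sqrt(rowSums(nrm^2))))
  # fixed scales change the trade-off as computed by hand
  nrm_s <- cbind((10 - front3[, 1]) / 10, (front3[, 2] - 1) / 0.5)
  expect_equal(select_ideal_point(front3, senses, scale = c(10, 0.5)),
               which.min(sqrt(rowSums(nrm_s^2))))
  expect_error(select_ideal_point(front3[0, , drop = FALSE], senses), "empty")
})

test_that("the search solves a Schaffer-type biobjective toy", {
  cfg <- nsga2_config(pop_size = 40, generations = 60,
                      gaba_bounds = c(-5, 5), senses = c("min", "min"),
                      mutation_rate = 0.1, seed = 31)
  toy <- function(dec) cbind(dec$gaba^2, (dec$gaba - 2)^2)
  res <- nsga2_evolve(cfg, toy)
  inside <- res$front$gaba >= -0.1 & res$front$gaba <= 2.1
  expect_gte(mean(inside), 0.9)
  expect_s3_class(res, "pareto_result")
})

test_that("elitism makes the single-objective best non-increasing", {
  cfg <- nsga2_config(pop_size = 20, generations = 40,
                      senses = c("min"), mutation_rate = 0.2, seed = 32)
  f <- function(dec) cbind((dec$gaba - 17)^2 + (dec$dpt - 33)^2)
  res <- nsga2_evolve(cfg, f)
  expect_true(all(diff(res$log$best_1) <= 1e-12))
})

test_that("runs are deterministic and respect the decision bounds", {
  cfg <- nsga2_config(pop_size = 24, generations = 25, seed = 33)
  sf <- default_surfaces("Atabaki")
  f <- function(dec) {
    vapply(trait_names(), function(tr) {
      true_response(sf[[tr]], dec$gaba, dec$stress, dec$dpt)
    }, numeric(nrow(dec)))
  }
  r1 <- nsga2_evolve(cfg, f)
  r2 <- nsga2_evolve(cfg, f)
  expect_identical(r1$front, r2$front)
  expect_identical(r1$ideal, r2$ideal)
  expect_true(all(r1$front$gaba >= 0 & r1$front$gaba <= 40))
  expect_true(all(r1$front$dpt >= 14 & r1$front$dpt <= 45))
  expect_true(all(r1$front$stress %in% stress_levels()))
  # final front is internally non-dominated
  fronts <- fast_nondominated_sort(as.matrix(r1$front[, trait_names()]),
                                   trait_senses())
  expect_length(fronts, 1)
})

test_that("configuration invariants are enforced", {
  expect_error(nsga2_config(crossover_rate = 1.2), "rates")
  expect_error(nsga2_config(gaba_bounds = c(5, 5)), "bounds")
  expect_error(nsga2_config(senses = c("max", "up")), "senses")
})

test_that("surrogate objectives are deterministic, bounded and clipped", {
  ds <- generate_dataset(synthetic_config(noise_cv = 0, seed = 4))
  enc <- encode_inputs(ds)
  plan <- make_split(192, 5, seed = 9)
  xp <- zscore_fit(enc$X[plan$train, ])
  yp <- zscore_fit(enc$Y[plan$train, ])
  Xs <- zscore_apply(enc$X, xp)
  Ys <- zscore_apply(enc$Y, yp)
  models <- lapply(trait_names(), function(tr) {
    grnn_fit(Xs[plan$train, ], Ys[plan$train, tr], sigma = 0.05)
  })
  names(models) <- trait_names()
  surr <- surrogate_set("Atabaki", "grnn", models, xp, yp)
  f <- make_objective(surr)
  cond <- data.frame(gaba = 10, dpt = 30, stress = "S")
  o1 <- f(cond)
  expect_identical(o1, f(cond))
  # at a training condition a near-interpolating GRNN returns its targets
  i <- which(ds$gaba_mM == 10 & ds$stress == "S" & ds$dpt_days == 30)[1]
  expect_equal(unname(o1[1, ]), unname(enc$Y[i, ]), tolerance = 1e-6)
  # convex-combination bound, mapped back to original units
  rand <- data.frame(gaba = runif(20, 0, 40), dpt = runif(20, 14, 45),
                     stress = sample(stress_levels(), 20, replace = TRUE))
  or <- f(rand)
  for (j in seq_len(7)) {
    expect_true(all(or[, j] >= min(enc$Y[plan$train, j]) - 1e-9))
    expect_true(all(or[, j] <= max(enc$Y[plan$train, j]) + 1e-9))
  }
  # out-of-bounds decisions are clipped and counted
  expect_equal(attr(f, "clips")(), 0L)
  f(data.frame(gaba = 99, dpt = 30, stress = "C"))
  expect_equal(attr(f, "clips")(), 1L)
})
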