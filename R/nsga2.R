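# Elitist non-dominated sorting genetic algorithm (NSGA-II) over treatment
# space: two continuous genes (GABA dose, days post-treatment) and one
# categorical gene (stress category), evaluated against an arbitrary number
# of objectives with per-objective senses.

#' NSGA-II configuration
#'
#' Defaults follow the study settings: population 50, 200 generations,
#' crossover rate 0.8; the mutation rate is 0.05 for 'Atabaki' runs and
#' 0.01 for 'Rabab' runs.
#'
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param crossover_rate Probability of two-point crossover per mating.
#' @param mutation_rate Per-gene mutation probability.
#' @param gaba_bounds,dpt_bounds Decision bounds (mM / days).
#' @param stress_lv Categorical gene levels.
#' @param senses Character vector of `"max"`/`"min"`, one per objective.
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return Object of class `nsga2_config`.
#' @export
nsga2_config <- function(pop_size = 50, generations = 200,
                         crossover_rate = 0.8, mutation_rate = 0.05,
                         gaba_bounds = c(0, 40), dpt_bounds = c(14, 45),
                         stress_lv = stress_levels(),
                         senses = trait_senses(), seed = 1L) {
  stopifnot(pop_size >= 2, generations >= 1)
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    stopf("rates must lie in [0, 1]")
  }
  if (!all(is.finite(gaba_bounds)) || gaba_bounds[1] >= gaba_bounds[2] ||
      !all(is.finite(dpt_bounds)) || dpt_bounds[1] >= dpt_bounds[2]) {
    stopf("decision bounds must be finite with lower < upper")
  }
  if (!all(senses %in% c("max", "min"))) stopf("senses must be 'max'/'min'")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 gaba_bounds = gaba_bounds, dpt_bounds = dpt_bounds,
                 stress_lv = stress_lv, senses = senses,
                 seed = as.integer(seed)),
            class = "nsga2_config")
}

# Orient an objective matrix so that smaller is always better.
orient <- function(obj, senses) {
  obj <- as_num_matrix(obj, "obj")
  sweep(obj, 2, ifelse(senses == "max", -1, 1), `*`)
}

#' Pareto dominance
#'
#' `a` dominates `b` when it is no worse in every objective (per sense) and
#' strictly better in at least one.
#'
#' @param a,b Objective vectors of equal length.
#' @param senses `"max"`/`"min"` per objective.
#' @return Logical scalar.
#' @export
dominates <- function(a, b, senses = trait_senses()) {
  stopifnot(length(a) == length(b), length(a) == length(senses))
  s <- ifelse(senses == "max", -1, 1)
  am <- s * a
  bm <- s * b
  all(am <= bm) && any(am < bm)
}

#' Fast non-dominated sorting
#'
#' Deb's bookkeeping algorithm: front 1 is the non-dominated set, front
#' i + 1 the non-dominated set once fronts <= i are removed.  Order within
#' fronts is the stable input order.
#'
#' @param obj Objective matrix (rows = individuals).
#' @param senses `"max"`/`"min"` per column.
#' @return List of integer vectors of row indices, one per front.
#' @export
fast_nondominated_sort <- function(obj, senses = trait_senses()) {
  om <- orient(obj, senses)
  n <- nrow(om)
  # pairwise dominance via vectorised column comparisons
  dom <- matrix(FALSE, n, n)
  for (j in seq_len(ncol(om))) {
    cj <- om[, j]
    leq <- outer(cj, cj, `<=`)
    lt <- outer(cj, cj, `<`)
    if (j == 1) {
      all_leq <- leq
      any_lt <- lt
    } else {
      all_leq <- all_leq & leq
      any_lt <- any_lt | lt
    }
  }
  dom <- all_leq & any_lt  # dom[i, j]: i dominates j
  n_dominators <- colSums(dom)
  fronts <- list()
  current <- which(n_dominators == 0)
  assigned <- 0L
  while (length(current)) {
    fronts[[length(fronts) + 1]] <- current
    assigned <- assigned + length(current)
    if (assigned >= n) break
    n_dominators <- n_dominators - colSums(dom[current, , drop = FALSE])
    n_dominators[unlist(fronts)] <- NA_integer_
    current <- which(!is.na(n_dominators) & n_dominators == 0)
  }
  fronts
}

#' Crowding distance within a front
#'
#' Per objective the front is sorted, the two extremes receive infinite
#' distance and interior points accumulate the min-max-normalised gap
#' between their neighbours; an objective that is constant across the front
#' contributes nothing.
#'
#' @param obj Objective matrix of the front members (rows).
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(obj) {
  obj <- as_num_matrix(obj, "obj")
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (j in seq_len(ncol(obj))) {
    v <- obj[, j]
    rng <- max(v) - min(v)
    if (rng == 0) next
    ord <- order(v)
    d[ord[c(1, n)]] <- Inf
    d[ord[2:(n - 1)]] <- d[ord[2:(n - 1)]] +
      (v[ord[3:n]] - v[ord[1:(n - 2)]]) / rng
  }
  d
}

#' Utopia-nearest member of a Pareto front
#'
#' Objectives are oriented so that smaller is better, shifted so that the
#' front's per-objective best is 0, and normalised either by the front's
#' min-max range (`scale = NULL`) or by fixed per-objective scales (e.g.
#' the traits' training standard deviations); the member with the smallest
#' Euclidean distance to the all-best corner is returned (first in stable
#' order on ties).
#'
#' Fixed scales make the selection robust on fronts where an objective
#' varies only at noise level: min-max normalisation stretches any residual
#' variation to a full unit of distance, so the selected compromise can be
#' driven by replicate noise rather than by real trade-offs.
#'
#' @param obj Objective matrix of the front members.
#' @param senses `"max"`/`"min"` per column.
#' @param scale Optional positive per-objective scales (original units).
#' @return Integer row index of the selected member.
#' @export
select_ideal_point <- function(obj, senses = trait_senses(), scale = NULL) {
  om <- orient(obj, senses)
  if (nrow(om) == 0) stopf("empty front")
  lo <- apply(om, 2, min)
  if (is.null(scale)) {
    hi <- apply(om, 2, max)
    scale <- pmax(hi - lo, .Machine$double.eps)
  } else {
    stopifnot(length(scale) == ncol(om), all(scale > 0))
  }
  nrm <- sweep(sweep(om, 2, lo), 2, scale, `/`)
  which.min(sqrt(rowSums(nrm^2)))
}

clip <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

# Binary tournament on (rank, crowding): lower rank wins, ties by larger
# crowding distance, further ties by the first contender.
tournament_pick <- function(rank, crowd, i, j) {
  if (rank[i] < rank[j]) return(i)
  if (rank[j] < rank[i]) return(j)
  if (crowd[i] >= crowd[j]) i else j
}

#' Run the NSGA-II search
#'
#' Seeded uniform initialisation within bounds; each generation applies
#' binary tournament selection on (rank, crowding distance), two-point
#' crossover on the 3-gene chromosome (gaba, dpt, stress), per-gene
#' mutation (Gaussian perturbation with sd = 10% of the range for the
#' continuous genes, clipped to bounds; uniform category reset for stress),
#' and elitist mu+lambda environmental selection back to the population
#' size.
#'
#' @param config An [nsga2_config()].
#' @param objective_fn Function mapping a decision `data.frame` with
#'   columns `gaba`, `dpt`, `stress` (n rows) to an n x m objective matrix
#'   in the order of `config$senses`.
#' @param ideal_scale Optional per-objective scales passed to
#'   [select_ideal_point()]; `NULL` uses front min-max normalisation.
#' @return Object of class `pareto_result`: `front` (decisions +
#'   objectives of the final non-dominated set), `ideal` (the selected
#'   ideal point, one row), `config` and `log` (per-generation front size
#'   and oriented per-objective bests).
#' @export
nsga2_evolve <- function(config, objective_fn, ideal_scale = NULL) {
  stopifnot(inherits(config, "nsga2_config"))
  set.seed(config$seed)
  np <- config$pop_size
  m <- length(config$senses)
  dec <- data.frame(
    gaba = runif(np, config$gaba_bounds[1], config$gaba_bounds[2]),
    dpt = runif(np, config$dpt_bounds[1], config$dpt_bounds[2]),
    stress = sample(config$stress_lv, np, replace = TRUE),
    stringsAsFactors = FALSE)
  obj <- as_num_matrix(objective_fn(dec), "objectives")
  if (nrow(obj) != np || ncol(obj) != m) {
    stopf("objective_fn returned a %dx%d matrix, expected %dx%d",
          nrow(obj), ncol(obj), np, m)
  }
  log <- vector("list", config$generations)

  rank_of <- function(fronts, n) {
    r <- integer(n)
    for (f in seq_along(fronts)) r[fronts[[f]]] <- f
    r
  }
  crowd_of <- function(fronts, obj) {
    cd <- numeric(nrow(obj))
    for (fr in fronts) cd[fr] <- crowding_distance(obj[fr, , drop = FALSE])
    cd
  }

  for (gen in seq_len(config$generations)) {
    fronts <- fast_nondominated_sort(obj, config$senses)
    rank <- rank_of(fronts, np)
    crowd <- crowd_of(fronts, obj)

    # offspring by tournament + two-point crossover + per-gene mutation
    child_g <- numeric(np)
    child_t <- numeric(np)
    child_s <- character(np)
    i <- 1L
    while (i <= np) {
      p1 <- tournament_pick(rank, crowd, sample.int(np, 1), sample.int(np, 1))
      p2 <- tournament_pick(rank, crowd, sample.int(np, 1), sample.int(np, 1))
      c1 <- c(dec$gaba[p1], dec$dpt[p1])
      s1 <- dec$stress[p1]
      c2 <- c(dec$gaba[p2], dec$dpt[p2])
      s2 <- dec$stress[p2]
      if (runif(1) < config$crossover_rate) {
        cuts <- sort(sample(0:3, 2))
        swap <- seq_len(3) > cuts[1] & seq_len(3) <= cuts[2]
        g1 <- list(c1[1], c1[2], s1)
        g2 <- list(c2[1], c2[2], s2)
        tmp <- g1
        g1[swap] <- g2[swap]
        g2[swap] <- tmp[swap]
        c1 <- c(g1[[1]], g1[[2]])
        s1 <- g1[[3]]
        c2 <- c(g2[[1]], g2[[2]])
        s2 <- g2[[3]]
      }
      for (child in list(list(c = c1, s = s1), list(c = c2, s = s2))) {
        if (i > np) break
        g <- child$c[1]
        t <- child$c[2]
        s <- child$s
        if (runif(1) < config$mutation_rate) {
          g <- g + rnorm(1, 0, 0.1 * diff(config$gaba_bounds))
        }
        if (runif(1) < config$mutation_rate) {
          t <- t + rnorm(1, 0, 0.1 * diff(config$dpt_bounds))
        }
        if (runif(1) < config$mutation_rate) {
          s <- sample(config$stress_lv, 1)
        }
        child_g[i] <- clip(g, config$gaba_bounds)
        child_t[i] <- clip(t, config$dpt_bounds)
        child_s[i] <- s
        i <- i + 1L
      }
    }
    child_dec <- data.frame(gaba = child_g, dpt = child_t, stress = child_s,
                            stringsAsFactors = FALSE)
    child_obj <- as_num_matrix(objective_fn(child_dec), "objectives")

    # mu + lambda elitist environmental selection
    all_dec <- rbind(dec, child_dec)
    all_obj <- rbind(obj, child_obj)
    fronts <- fast_nondominated_sort(all_obj, config$senses)
    keep <- integer(0)
    for (fr in fronts) {
      if (length(keep) + length(fr) <= np) {
        keep <- c(keep, fr)
      } else {
        cd <- crowding_distance(all_obj[fr, , drop = FALSE])
        need <- np - length(keep)
        keep <- c(keep, fr[order(-cd)[seq_len(need)]])
        break
      }
    }
    dec <- all_dec[keep, , drop = FALSE]
    rownames(dec) <- NULL
    obj <- all_obj[keep, , drop = FALSE]

    om <- orient(obj, config$senses)
    log[[gen]] <- c(generation = gen,
                    front_size = length(fronts[[1]]),
                    stats::setNames(apply(om, 2, min),
                                    paste0("best_", seq_len(m))))
  }

  fronts <- fast_nondominated_sort(obj, config$senses)
  f1 <- fronts[[1]]
  front_dec <- dec[f1, , drop = FALSE]
  rownames(front_dec) <- NULL
  front_obj <- obj[f1, , drop = FALSE]
  ideal_i <- select_ideal_point(front_obj, config$senses, scale = ideal_scale)
  front <- cbind(front_dec, front_obj)
  structure(list(front = front,
                 ideal = front[ideal_i, , drop = FALSE],
                 config = config,
                 log = as.data.frame(do.call(rbind, log))),
            class = "pareto_result")
}

#' @export
print.pareto_result <- function(x, ...) {
  cat(sprintf("NSGA-II result: final front of %d solutions (%d generations, pop %d)\n",
              nrow(x$front), x$config$generations, x$config$pop_size))
  cat("ideal point:\n")
  print(x$ideal, row.names = FALSE)
  invisible(x)
}
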