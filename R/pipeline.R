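# End-to-end orchestration: generate/load -> encode/split/standardise ->
# fit + cross-validate the families -> compare/select -> NSGA-II -> report.

#' Pipeline configuration
#'
#' Exactly one data source: either `synthetic` (a list of
#' [synthetic_config()]s, one per cultivar) or `csv` (a dataset written by
#' [write_stress_dataset()], possibly holding several cultivars).  The
#' global `seed` deterministically derives a sub-seed for every stochastic
#' stage (data generation, splitting, model fits, optimisation), so a rerun
#' with the same configuration is bit-identical.
#'
#' @param synthetic List of [synthetic_config()] objects, or `NULL`.
#' @param csv Path to a dataset CSV, or `NULL`.
#' @param cultivars Cultivars to process (default: those found in the
#'   source).
#' @param families Surrogate families to fit and compare.
#' @param k Cross-validation folds.
#' @param train_frac Training fraction of the 85/15 split.
#' @param search_spaces Optional named list of per-family candidate grids.
#' @param nsga Named list of [nsga2_config()] per cultivar; by default the
#'   study settings with mutation rate 0.05 ('Atabaki') / 0.01 ('Rabab',
#'   and any other cultivar).
#' @param out_dir Output directory for artifacts (`NULL` = don't write).
#' @param seed Global integer seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, csv = NULL, cultivars = NULL,
                            families = c("grnn", "rbf", "rf", "svr"),
                            k = 5, train_frac = 0.85, search_spaces = NULL,
                            nsga = NULL, out_dir = NULL, seed = 1L) {
  if (is.null(synthetic) == is.null(csv)) {
    stopf("exactly one data source required: `synthetic` or `csv`")
  }
  if (!is.null(synthetic)) {
    if (inherits(synthetic, "synthetic_config")) synthetic <- list(synthetic)
    ok <- all(vapply(synthetic, inherits, logical(1), "synthetic_config"))
    if (!ok) stopf("`synthetic` must be a list of synthetic_config objects")
  }
  families <- match.arg(families, surrogate_families, several.ok = TRUE)
  structure(list(synthetic = synthetic, csv = csv, cultivars = cultivars,
                 families = families, k = as.integer(k),
                 train_frac = train_frac, search_spaces = search_spaces,
                 nsga = nsga, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

default_mutation_rate <- function(cultivar) {
  if (identical(cultivar, "Atabaki")) 0.05 else 0.01
}

load_pipeline_data <- function(config) {
  if (!is.null(config$synthetic)) {
    datasets <- lapply(config$synthetic, generate_dataset)
  } else {
    full <- read_stress_dataset(config$csv)
    datasets <- split(full, full$cultivar)
    datasets <- lapply(datasets, function(d) {
      class(d) <- c("stress_dataset", "data.frame")
      d
    })
  }
  names(datasets) <- vapply(datasets, function(d) unique(d$cultivar)[1],
                            character(1))
  if (!is.null(config$cultivars)) {
    missing <- setdiff(config$cultivars, names(datasets))
    if (length(missing)) {
      stopf("cultivar(s) not in data source: %s",
            paste(missing, collapse = ", "))
    }
    datasets <- datasets[config$cultivars]
  }
  datasets
}

fit_family <- function(family, cultivar, enc, plan, Xs, Ys, y_params,
                       space, seed) {
  models <- list()
  best <- list()
  rows <- list()
  for (tr in trait_names()) {
    cv <- cross_validate(family, Xs, Ys[, tr], plan, space = space,
                         seed = derive_seed(seed, paste0(family, tr)))
    models[[tr]] <- cv$model
    best[[tr]] <- cv$best
    for (sub in c("training", "testing")) {
      idx <- if (sub == "training") plan$train else plan$test
      est_s <- predict(cv$model, Xs[idx, , drop = FALSE])
      obs_s <- Ys[idx, tr]
      est_o <- est_s * y_params$sd[tr] + y_params$mean[tr]
      obs_o <- enc$Y[idx, tr]
      for (scale in c("original", "standardized")) {
        m <- if (scale == "original") metric_row(obs_o, est_o) else
          metric_row(obs_s, est_s)
        rows[[length(rows) + 1]] <- data.frame(
          cultivar = cultivar, family = family, trait = tr, subset = sub,
          metric = names(m), value = unname(m), scale = scale)
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      cultivar = cultivar, family = family, trait = tr, subset = "cv",
      metric = "RMSE", value = cv$cv_rmse, scale = "standardized")
  }
  list(family = family, metrics = do.call(rbind, rows), plan = plan,
       models = models, hyperparams = best)
}

#' Run the full modelling and optimisation pipeline
#'
#' Per cultivar: encode the dataset, make the 85/15 split with k folds, fit
#' z-score parameters on the training rows, cross-validate every requested
#' family per trait, rank the families ([compare_models()]), couple the
#' winning family's surrogate set to NSGA-II and select the ideal point.
#' When `out_dir` is set, writes `data/`, `metrics/`, `pareto/`,
#' `summary.csv` and `report.json` artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_report`: per-cultivar results (`dataset`,
#'   `plan`, `reports`, `comparison`, `surrogates`, `pareto`, `ideal`) plus
#'   a Table-style `summary` data.frame (one row per cultivar: optimal
#'   stress, dose, day and the seven predicted trait values).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  datasets <- load_pipeline_data(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    for (d in c("", "data", "metrics", "pareto")) {
      dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
    }
  }
  results <- list()
  summary_rows <- list()
  all_metrics <- list()
  for (cultivar in names(datasets)) {
    ds <- datasets[[cultivar]]
    enc <- encode_inputs(ds)
    n <- nrow(enc$X)
    plan <- make_split(n, k = config$k,
                       seed = derive_seed(config$seed, paste0("split", cultivar)),
                       train_frac = config$train_frac)
    x_params <- zscore_fit(enc$X[plan$train, , drop = FALSE])
    y_params <- zscore_fit(enc$Y[plan$train, , drop = FALSE])
    Xs <- zscore_apply(enc$X, x_params)
    Ys <- zscore_apply(enc$Y, y_params)

    reports <- lapply(config$families, function(fam) {
      fit_family(fam, cultivar, enc, plan, Xs, Ys, y_params,
                 space = config$search_spaces[[fam]],
                 seed = derive_seed(config$seed, paste0("fit", cultivar, fam)))
    })
    names(reports) <- config$families

    if (length(reports) > 1) {
      comparison <- compare_models(reports)
      best_family <- comparison$best
    } else {
      comparison <- list(best = config$families[1],
                         ranking = NULL,
                         table = reports[[1]]$metrics)
      best_family <- config$families[1]
    }
    best_rep <- reports[[best_family]]
    surr <- surrogate_set(cultivar, best_family, best_rep$models,
                          x_params, y_params, best_rep$hyperparams)

    ncfg <- config$nsga[[cultivar]] %||% nsga2_config(
      mutation_rate = default_mutation_rate(cultivar),
      seed = derive_seed(config$seed, paste0("nsga", cultivar)))
    objective <- make_objective(surr, ncfg$gaba_bounds, ncfg$dpt_bounds)
    pareto <- nsga2_evolve(ncfg, objective,
                           ideal_scale = unname(y_params$sd[trait_names()]))

    ideal <- pareto$ideal
    summary_rows[[cultivar]] <- data.frame(
      cultivar = cultivar, best_family = best_family,
      stress = ideal$stress, gaba_mM = ideal$gaba, dpt_days = ideal$dpt,
      ideal[, trait_names(), drop = FALSE])
    all_metrics[[cultivar]] <- do.call(rbind,
                                       lapply(reports, `[[`, "metrics"))
    results[[cultivar]] <- list(
      dataset = ds, plan = plan, x_params = x_params, y_params = y_params,
      reports = reports, comparison = comparison, surrogates = surr,
      pareto = pareto, ideal = ideal, clipped = attr(objective, "clips")())

    if (!is.null(out_dir)) {
      write_stress_dataset(ds, file.path(out_dir, "data",
                                         paste0(cultivar, ".csv")))
      front <- pareto$front
      write.csv(front, file.path(out_dir, "pareto",
                                 paste0("front_", cultivar, ".csv")),
                row.names = FALSE)
      jsonlite::write_json(
        list(cultivar = cultivar, best_family = best_family,
             ideal = as.list(ideal),
             nsga = unclass(ncfg)[c("pop_size", "generations",
                                    "crossover_rate", "mutation_rate",
                                    "seed")],
             split = list(n = plan$n, k = plan$k, seed = plan$seed),
             hyperparams = best_rep$hyperparams),
        file.path(out_dir, "pareto", paste0("ideal_", cultivar, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  metrics <- do.call(rbind, all_metrics)
  rownames(metrics) <- NULL
  if (!is.null(out_dir)) {
    write.csv(metrics, file.path(out_dir, "metrics", "metrics.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, families = config$families, k = config$k,
           train_frac = config$train_frac,
           cultivars = names(datasets),
           summary = summary),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  structure(list(results = results, summary = summary, metrics = metrics,
                 config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("gabaopt pipeline run\n")
  cat(sprintf("cultivars: %s | families: %s\n",
              paste(names(x$results), collapse = ", "),
              paste(x$config$families, collapse = ", ")))
  cat("optimal treatment summary:\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
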