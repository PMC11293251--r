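# Synthetic factorial stress-experiment generator.
#
# Each trait is a smooth phenomenological surface over (GABA dose, stress
# category, days post-treatment).  Traits that are maximised (enzymes,
# protein) follow
#   value = baseline(stress) + amplitude * B_g(gaba) * B_t(dpt)
# with a Gaussian dose bump B_g centred at the optimal dose and an
# asymmetric Gaussian time bump B_t peaking mid-experiment.  Traits that are
# minimised (MDA, H2O2) follow
#   value = baseline(stress) * G(gaba) * T(dpt)
# with a saturating dose-suppression G (non-increasing, plateauing at a
# positive floor) and a trait-specific time profile T: a saturating decay
# for H2O2, an asymmetric valley for MDA.

#' Construct a trait response surface
#'
#' @param name Trait name (one of [trait_names()]).
#' @param sense `"max"` (bump-type surface) or `"min"` (decay-type surface).
#' @param baseline Named numeric vector of baselines per stress category, in
#'   trait units. For `"max"` traits the combined-stress baseline must exceed
#'   the single-stress baselines, which must exceed control.
#' @param amplitude Treatment effect size in trait units (`"max"` traits).
#' @param gaba_opt,gaba_width Centre (mM) and width (mM) of the Gaussian dose
#'   bump (`"max"` traits).
#' @param time_peak,time_width_left,time_width_right Peak (days) and
#'   asymmetric widths (days) of the time bump (`"max"` traits).
#' @param gaba_halfmax Dose (mM) at which half of the suppressible fraction
#'   of a `"min"` trait is removed.
#' @param gaba_floor Fraction of the baseline that is not suppressible by
#'   GABA (plateau of the dose response), in (0, 1).
#' @param time_profile For `"min"` traits, either
#'   `list(type = "plateau", rate = , floor = , ref = )` (saturating
#'   exponential decay from the reference day) or
#'   `list(type = "valley", center = , width_left = , width_right = ,
#'   depth = )` (asymmetric inverted bump).
#' @return An object of class `trait_surface`.
#' @seealso [true_response()], [default_surfaces()]
#' @export
trait_surface <- function(name, sense, baseline,
                          amplitude = NULL,
                          gaba_opt = NULL, gaba_width = NULL,
                          time_peak = NULL, time_width_left = NULL,
                          time_width_right = NULL,
                          gaba_halfmax = NULL, gaba_floor = 0.2,
                          time_profile = NULL) {
  sense <- match.arg(sense, c("max", "min"))
  if (is.null(names(baseline)) || !all(stress_levels() %in% names(baseline))) {
    stopf("`baseline` must be named over all stress levels (%s)",
          paste(stress_levels(), collapse = ", "))
  }
  baseline <- baseline[stress_levels()]
  if (any(baseline <= 0)) stopf("baselines must be strictly positive")
  if (sense == "max") {
    ok <- baseline[["DxS"]] > baseline[["D"]] &&
      baseline[["DxS"]] > baseline[["S"]] &&
      baseline[["S"]] > baseline[["C"]] && baseline[["D"]] > baseline[["C"]]
    if (!ok) stopf("'max' trait '%s': need baseline DxS > D, S and D, S > C", name)
    stopifnot(amplitude > 0, gaba_width > 0,
              time_width_left > 0, time_width_right > 0)
  } else {
    stopifnot(gaba_halfmax > 0, gaba_floor > 0, gaba_floor < 1)
    type <- time_profile$type %||% "plateau"
    if (!type %in% c("plateau", "valley")) {
      stopf("unknown time profile '%s'", type)
    }
  }
  structure(list(name = name, sense = sense, baseline = baseline,
                 amplitude = amplitude, gaba_opt = gaba_opt,
                 gaba_width = gaba_width, time_peak = time_peak,
                 time_width_left = time_width_left,
                 time_width_right = time_width_right,
                 gaba_halfmax = gaba_halfmax, gaba_floor = gaba_floor,
                 time_profile = time_profile),
            class = "trait_surface")
}

# Asymmetric Gaussian bump with distinct widths either side of the mode.
asym_bump <- function(t, t0, w_left, w_right) {
  w <- ifelse(t < t0, w_left, w_right)
  exp(-(t - t0)^2 / (2 * w^2))
}

# Saturating dose suppression: Gaussian-in-dose decay towards a floor with
# half the suppressible fraction removed at `halfmax`.
dose_suppression <- function(gaba, halfmax, floor) {
  floor + (1 - floor) * exp(-log(2) * (gaba / halfmax)^2)
}

min_time_factor <- function(surface, dpt) {
  tp <- surface$time_profile
  switch(tp$type,
    plateau = tp$floor + (1 - tp$floor) * exp(-tp$rate * (dpt - tp$ref)),
    valley = 1 - tp$depth * asym_bump(dpt, tp$center, tp$width_left,
                                      tp$width_right)
  )
}

#' Evaluate the noiseless response surface of a trait
#'
#' @param surface A [trait_surface()].
#' @param gaba GABA dose(s), mM.
#' @param stress Stress category (scalar or vector of [stress_levels()]).
#' @param dpt Days post-treatment.
#' @return Numeric vector of noiseless trait values (trait units).
#' @export
true_response <- function(surface, gaba, stress, dpt) {
  stopifnot(inherits(surface, "trait_surface"))
  if (!all(stress %in% stress_levels())) {
    bad <- unique(stress[!stress %in% stress_levels()])
    stopf("unknown stress category: %s", paste(bad, collapse = ", "))
  }
  b <- surface$baseline[stress]
  if (surface$sense == "max") {
    bg <- exp(-(gaba - surface$gaba_opt)^2 / (2 * surface$gaba_width^2))
    bt <- asym_bump(dpt, surface$time_peak, surface$time_width_left,
                    surface$time_width_right)
    unname(b + surface$amplitude * bg * bt)
  } else {
    g <- dose_suppression(gaba, surface$gaba_halfmax, surface$gaba_floor)
    unname(b * g * min_time_factor(surface, dpt))
  }
}

# Table-2-analogue optima used to calibrate the default surfaces: value of
# each trait at (gaba = 20 mM, stress = DxS, dpt = 25 d).
.calibration_targets <- list(
  Atabaki = c(protein = 0.80, APX = 50.63, SOD = 0.54, POD = 1.53,
              CAT = 4.42, MDA = 0.12, H2O2 = 0.44),
  Rabab = c(protein = 0.69, APX = 51.51, SOD = 0.53, POD = 1.72,
            CAT = 5.66, MDA = 0.15, H2O2 = 0.55)
)

#' Default trait surfaces for a cultivar
#'
#' The 'Atabaki' parameterisation places the shared enzymatic optimum at
#' 20 mM GABA, 25 days post-treatment under combined drought-salinity
#' stress, with noiseless optimum values calibrated to the reported
#' treatment-optimisation estimates; 'Rabab' rescales baselines and
#' amplitudes per trait so its optimum matches the second cultivar's
#' estimates.
#'
#' @param cultivar `"Atabaki"` or `"Rabab"`.
#' @param gaba_opt,time_peak Optional overrides of the shared optimum.
#' @return Named list of seven [trait_surface()] objects.
#' @export
default_surfaces <- function(cultivar = "Atabaki", gaba_opt = 20,
                             time_peak = 25) {
  cultivar <- match.arg(cultivar, c("Atabaki", "Rabab"))
  base <- list(
    protein = list(b = c(C = 0.40, D = 0.46, S = 0.49, DxS = 0.62), A = 0.18),
    APX = list(b = c(C = 22, D = 27, S = 29, DxS = 38), A = 12.63),
    SOD = list(b = c(C = 0.26, D = 0.31, S = 0.33, DxS = 0.41), A = 0.13),
    POD = list(b = c(C = 0.70, D = 0.87, S = 0.93, DxS = 1.15), A = 0.38),
    CAT = list(b = c(C = 2.0, D = 2.5, S = 2.65, DxS = 3.3), A = 1.12)
  )
  # per-trait rescale so each cultivar's noiseless optimum hits its target
  scale <- .calibration_targets[[cultivar]] / .calibration_targets[["Atabaki"]]
  out <- lapply(names(base), function(tr) {
    trait_surface(tr, "max",
                  baseline = base[[tr]]$b * scale[[tr]],
                  amplitude = base[[tr]]$A * scale[[tr]],
                  gaba_opt = gaba_opt, gaba_width = 12,
                  time_peak = time_peak, time_width_left = 6,
                  time_width_right = 12)
  })
  names(out) <- names(base)

  # oxidative markers: stress-elevated and strongly GABA-suppressed, with
  # the protective effect saturating past the optimal dose; MDA falls to a
  # mid-experiment minimum and rises again late (ending above its early
  # value), H2O2 decays monotonically towards a plateau
  g20 <- dose_suppression(gaba_opt, halfmax = 6, floor = 0.2)
  min_spread <- c(C = 0.90, D = 0.95, S = 0.98, DxS = 1)
  mda_valley <- list(type = "valley", center = time_peak, width_left = 10,
                     width_right = 6, depth = 0.5)
  mda_t25 <- 1 - 0.5 * asym_bump(time_peak, time_peak, 10, 6)
  out$MDA <- trait_surface("MDA", "min",
    baseline = .calibration_targets[[cultivar]][["MDA"]] /
      (g20 * mda_t25) * min_spread,
    gaba_halfmax = 6, gaba_floor = 0.2, time_profile = mda_valley)
  h2o2_profile <- list(type = "plateau", rate = 0.15, floor = 0.7, ref = 14)
  h2o2_t25 <- 0.7 + 0.3 * exp(-0.15 * (time_peak - 14))
  out$H2O2 <- trait_surface("H2O2", "min",
    baseline = .calibration_targets[[cultivar]][["H2O2"]] /
      (g20 * h2o2_t25) * min_spread,
    gaba_halfmax = 6, gaba_floor = 0.2, time_profile = h2o2_profile)
  out
}

#' Configuration of the synthetic factorial experiment
#'
#' Defaults reproduce the study design: four GABA doses (0, 10, 20, 40 mM),
#' four stress categories, three sampling days (14, 30, 45) and four
#' biological replicates, i.e. 192 samples per cultivar.
#'
#' @param cultivar Cultivar label.
#' @param gaba_levels Strictly increasing doses, mM.
#' @param stress_lv Stress categories (subset of [stress_levels()]).
#' @param dpt_levels Strictly increasing sampling days.
#' @param n_replicates Biological replicates per condition, >= 1.
#' @param surfaces Named list of seven [trait_surface()] objects; defaults to
#'   [default_surfaces()] of the cultivar.
#' @param noise_cv Replicate-level coefficient of variation of the
#'   multiplicative Gaussian noise (>= 0).
#' @param seed Integer seed controlling replicate noise.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(cultivar = "Atabaki",
                             gaba_levels = c(0, 10, 20, 40),
                             stress_lv = stress_levels(),
                             dpt_levels = c(14, 30, 45),
                             n_replicates = 4,
                             surfaces = default_surfaces(cultivar),
                             noise_cv = 0.05,
                             seed = 1L) {
  stopifnot(length(gaba_levels) > 0, length(dpt_levels) > 0,
            length(stress_lv) > 0)
  if (is.unsorted(gaba_levels, strictly = TRUE)) {
    stopf("`gaba_levels` must be strictly increasing")
  }
  if (is.unsorted(dpt_levels, strictly = TRUE)) {
    stopf("`dpt_levels` must be strictly increasing")
  }
  if (!all(stress_lv %in% stress_levels())) {
    stopf("unknown stress category in `stress_lv`")
  }
  if (n_replicates < 1) stopf("`n_replicates` must be >= 1")
  if (noise_cv < 0) stopf("`noise_cv` must be >= 0")
  if (!setequal(names(surfaces), trait_names())) {
    stopf("`surfaces` must cover exactly the traits %s",
          paste(trait_names(), collapse = ", "))
  }
  structure(list(cultivar = cultivar, gaba_levels = gaba_levels,
                 stress_lv = stress_lv, dpt_levels = dpt_levels,
                 n_replicates = n_replicates,
                 surfaces = surfaces[trait_names()],
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic factorial stress dataset
#'
#' One row per (dose, stress, day, replicate) combination.  Observed values
#' are `true_response * (1 + eps)` with `eps ~ N(0, noise_cv)`, truncated at
#' a small positive floor (1e-6 of the stress baseline); a warning is issued
#' if more than 1% of draws had to be truncated.
#'
#' @param config A [synthetic_config()].
#' @return A `data.frame` of class `stress_dataset` with columns
#'   `cultivar, gaba_mM, stress, dpt_days, replicate` and the seven traits.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        dpt_days = config$dpt_levels,
                        stress = config$stress_lv,
                        gaba_mM = config$gaba_levels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("gaba_mM", "stress", "dpt_days", "replicate")]
  set.seed(config$seed)
  n <- nrow(design)
  n_trunc <- 0L
  traits <- lapply(config$surfaces, function(sf) {
    mu <- true_response(sf, design$gaba_mM, design$stress, design$dpt_days)
    obs <- mu * (1 + rnorm(n, 0, config$noise_cv))
    floor_v <- 1e-6 * unname(sf$baseline[design$stress])
    n_trunc <<- n_trunc + sum(obs < floor_v)
    pmax(obs, floor_v)
  })
  if (n_trunc > 0.01 * n * length(traits)) {
    warning(sprintf("noise truncation affected %d of %d draws (> 1%%)",
                    n_trunc, n * length(traits)))
  }
  out <- cbind(data.frame(cultivar = config$cultivar), design,
               as.data.frame(traits))
  class(out) <- c("stress_dataset", "data.frame")
  out
}

#' Analytic optimum of a synthetic configuration
#'
#' Returns the argmax, over the continuous design region, shared by all
#' bump-type (maximise) traits, together with the noiseless values of all
#' seven traits there.  The stress category is the baseline-maximising one.
#'
#' @param config A [synthetic_config()].
#' @return List with `gaba`, `stress`, `dpt` and `traits` (named values).
#' @export
true_optimum <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  sf_max <- Filter(function(s) s$sense == "max", config$surfaces)
  if (length(sf_max) == 0) stopf("config has no maximise traits")
  g_opts <- vapply(sf_max, `[[`, numeric(1), "gaba_opt")
  t_opts <- vapply(sf_max, `[[`, numeric(1), "time_peak")
  if (length(unique(g_opts)) != 1 || length(unique(t_opts)) != 1) {
    stopf("maximise traits must share gaba_opt and time_peak")
  }
  g_star <- min(max(g_opts[1], min(config$gaba_levels)), max(config$gaba_levels))
  t_star <- min(max(t_opts[1], min(config$dpt_levels)), max(config$dpt_levels))
  # baseline-maximising stress category, consistent across maximise traits
  picks <- vapply(sf_max, function(s) {
    names(which.max(s$baseline[config$stress_lv]))
  }, character(1))
  s_star <- picks[[1]]
  if (length(unique(picks)) != 1) {
    stopf("maximise traits disagree on the best stress category")
  }
  vals <- vapply(config$surfaces, true_response, numeric(1),
                 gaba = g_star, stress = s_star, dpt = t_star)
  list(gaba = g_star, stress = s_star, dpt = t_star, traits = vals)
}

#' Write / read a stress dataset as CSV
#'
#' Fixed column schema
#' `cultivar,gaba_mM,stress,dpt_days,replicate,protein,APX,SOD,POD,CAT,MDA,H2O2`
#' with stress serialised as the literal tokens C, D, S, DxS.
#'
#' @param dataset A `stress_dataset`.
#' @param path File path.
#' @return `read_stress_dataset` returns a `stress_dataset`;
#'   `write_stress_dataset` returns `path` invisibly.
#' @export
write_stress_dataset <- function(dataset, path) {
  cols <- c("cultivar", "gaba_mM", "stress", "dpt_days", "replicate",
            trait_names())
  stopifnot(all(cols %in% names(dataset)))
  out <- dataset[, cols]
  for (tr in trait_names()) {
    # full binary precision so that a round trip is bit-exact
    out[[tr]] <- sprintf("%.17g", out[[tr]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stress_dataset
#' @export
read_stress_dataset <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("cultivar", "gaba_mM", "stress", "dpt_days", "replicate",
            trait_names())
  missing <- setdiff(cols, names(out))
  if (length(missing)) {
    stopf("malformed dataset CSV, missing columns: %s",
          paste(missing, collapse = ", "))
  }
  bad <- which(!out$stress %in% stress_levels())
  if (length(bad)) {
    stopf("unknown stress token '%s' at row %d", out$stress[bad[1]], bad[1])
  }
  out <- out[, cols]
  class(out) <- c("stress_dataset", "data.frame")
  out
}
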