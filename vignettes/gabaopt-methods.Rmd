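---
title: "Methods: surrogate models, synthetic benchmark and treatment optimisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate models, synthetic benchmark and treatment optimisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabaopt)
```

`gabaopt` models seven physio-biochemical traits of stressed plants as
functions of three treatment variables — GABA dose (mM), stress category
(C, D, S, D×S) and days post-treatment (DPT) — and then searches the
treatment space for the combination that jointly maximises five
protective traits (protein, APX, SOD, POD, CAT) and minimises two
oxidative-damage markers (MDA, H₂O₂). This vignette documents the models,
the synthetic benchmark, the parameters that matter, and the design
decisions taken where the methodology was genuinely open.

## 1. Data model and preprocessing

A dataset is a full factorial table: one row per (dose, stress, day,
replicate). `encode_inputs()` maps a row to a 6-vector (dose, day, and a
one-hot stress block in fixed order C, D, S, D×S). One-hot coding was
chosen over an ordinal code because the kernel families (GRNN, RBF, SVR)
work on Euclidean distances, and an ordinal code would impose an
arbitrary "distance" between drought and salinity.

`make_split()` draws a seeded uniform permutation, assigns
`floor(0.85 n)` rows to training and the rest to testing, and deals the
training rows round-robin into *k* folds (sizes differ by ≤ 1). We use
k = 5 throughout: at n ≈ 163 training rows this leaves ~33 validation
rows per fold, a standard bias/variance compromise.

`zscore_fit()` standardises every input and target column by its
training-set mean and *population* standard deviation (divisor n — the
plain z-score formula, no finite-sample correction). Parameters are
fitted on training rows only; the test rows are transformed with the
training parameters (no leakage — property-tested). Targets are
standardised as well, which conditions the RBF/SVR solvers; predictions
are inverse-transformed before metrics and optimisation are reported in
original units.

## 2. The four surrogate families

All families share the fit/predict surface used by
`hyperparameter_search()` and `cross_validate()`.

**GRNN** (`grnn_fit()`): a one-pass kernel regressor. Prediction is the
convex combination Ŷ(x) = Σ Yᵢ wᵢ(x)/Σ wᵢ(x) with
wᵢ = exp(−‖x − xᵢ‖²/2σ²) on standardised inputs. One scalar bandwidth σ
per trait; the default grid is 20 log-spaced values in [0.05, 3]
standardised units (below ~0.05 the model memorises single replicates,
above ~3 it approaches the global mean; log spacing matches the
multiplicative role of σ). Exponents are stabilised by subtracting the
row maximum before exponentiation, so one weight is always exactly 1 and
the ratio can never underflow to 0/0 — the naive formula overflows for
distant queries at small σ. CV ties are broken towards the *larger*
(smoother) bandwidth.

**RBF network** (`rbf_fit()`): Gaussian hidden units
φᵢ(x) = exp(−‖x − cᵢ‖²/2s²) and a linear output layer without bias.
Centers come from k-means on the distinct input rows (k-means cannot
place more centers than distinct points; the count is capped
accordingly). The common width is the median nearest-neighbour distance
among centers, capped at twice the *minimum* nearest-neighbour distance:
the median alone leaves the square all-centers design numerically
singular whenever two centers nearly coincide, while the cap keeps the
Gram matrix well conditioned, so the all-centers network interpolates its
training data at vanishing ridge (residual < 1e-6 at λ = 1e-10,
property-tested to n = 50). Output weights solve the λ-ridge least
squares problem through a QR factorisation of the λ-augmented design —
mathematically identical to the normal equations but without squaring the
condition number. Default λ = 1e-8; the searched grid varies the number
of hidden units (8–64).

**Random forest** (`rf_fit()`, backed by the `randomForest` package):
K trees on n-sample bootstraps, ensemble prediction = arithmetic tree
mean, out-of-bag error from the ~36.8% of samples each tree never saw.
Defaults ntree = 500, node size 5, mtry = ⌊p/3⌋; the search varies mtry
(1–6) and node size (2, 5).

**ε-SVR** (`svr_fit()`, backed by the libsvm solver in `e1071`): Gaussian
kernel, dual coefficients βᵢ = aᵢ − aᵢ* exposed per training point; the
fit must satisfy Σβᵢ = 0, |βᵢ| ≤ C and the ε-tube KKT conditions to the
solver tolerance (1e-3), which `svr_kkt_residual()` checks explicitly.
Search grid: C ∈ {0.1, 1, 10, 100}, ε ∈ {0.01, 0.05, 0.1},
γ ∈ {0.05, 0.1, 0.5, 1} on standardised data.

Per-trait single-output models are used everywhere (7 models per family
and cultivar): RF and SVR are inherently single-output, and per-trait
bandwidths dominate GRNN accuracy, so uniformity was preferred.

## 3. Evaluation and model selection

`r_squared()`, `rmse()` and `mbe()` implement
R² = 1 − Σ(Ŷ−Y)²/Σ(Y−Ȳ)², RMSE = √(Σ(Ŷ−Y)²/n) and MBE = Σ(Ŷ−Y)/n
(positive = over-estimation). The identity RMSE² − MBE² = Var(error) is
property-tested to 1e-10. `cross_validate()` nests the hyperparameter
search: each fold is scored with hyperparameters chosen on the remaining
folds only, then a final search over all folds picks the configuration
used for the refit on the full training set.

`compare_models()` ranks families by mean test-set R² across the seven
traits (original units); differences below 1e-6 are tie-broken by the
lower mean test RMSE on standardised targets, then lexicographically —
the ranking is invariant to evaluation order. Metrics are recorded on
both scales because a mean over traits in original units would otherwise
be dominated by the trait with the largest numbers (APX).

## 4. The synthetic benchmark

No replicate-level data being available, the generator defines the
ground truth the pipeline is tested against. Each maximise-trait follows

  value = baseline(stress) + amplitude · B_g(dose) · B_t(day),

with B_g a Gaussian bump centred at the optimal dose (default 20 mM,
width 12 mM) and B_t an asymmetric Gaussian in time (peak 25 d, left
width 6 d, right width 12 d — so activities rise to a mid-experiment peak,
fall, and remain above their early values at 45 d). Each minimise-trait
follows

  value = baseline(stress) · G(dose) · T(day),

where G is a saturating dose suppression
(floor + (1 − floor)·exp(−ln2·(g/h)²), floor 0.2, half-suppression
h = 6 mM — protection saturates near the optimal dose rather than growing
indefinitely with concentration), and T is trait-specific: H₂O₂ decays
monotonically towards a plateau (rate 0.15/d, floor 0.7); MDA follows an
asymmetric *valley* (minimum at 25 d, widths 10/6 d, depth 0.5), i.e. it
falls while acclimation builds and rises again late, ending above its
14-day value. The valley is our reading of two qualitative observations
that are contradictory under any monotone profile (MDA both "decreases as
treatment progresses" and "is higher at 45 than at 14 DPT"); it also
gives the multi-objective problem a genuine interior time optimum.

Baselines are strictly ordered C < D < S < D×S for the enzymes (combined
stress elicits the strongest response) and mildly ordered
(0.90/0.95/0.98/1) for the oxidative markers. Noise is multiplicative
Gaussian with a 5% coefficient of variation per replicate (biochemical
assay errors scale with magnitude), truncated at 1e-6 of baseline with a
warning if truncation touches more than 1% of draws.

**Calibration.** The free parameters above were fixed once, by two
requirements: (i) the noiseless optimum values at (20 mM, D×S, 25 d)
equal the per-cultivar treatment-optimisation estimates the package
targets ('Rabab' rescales baselines and amplitudes per trait by the
ratio of its estimates to 'Atabaki''s); (ii) the utopia-nearest point of
the *analytic* Pareto front lies at that same treatment — which is the
generator's purpose, since optimum recovery is the package's end-to-end
acceptance surface. Requirement (ii) is what motivates the saturating
dose suppression and the MDA valley: if the damage markers kept improving
monotonically beyond the enzymatic optimum in dose or time, the
seven-objective compromise would necessarily sit away from it and no
optimiser could "recover" anything. One further parameter is set by the
surrogate rather than the biology: the enzyme dose-bump width (12 mM) is
wide enough that the dose-10 samples lie close to the peak; with a narrow
bump, kernel regression on the sampled doses {0, 10, 20, 40} displaces
its apparent dose optimum several mM to the right of 20 (the low dose-10
neighbour drags predictions at 20 down, while the empty 20–40 gap is
contamination-free), an artefact of the design grid, not of the surface.

**What the generator does not emulate:** cultivar × treatment
interactions beyond proportional rescaling, heteroscedasticity beyond the
CV model, assay-specific detection limits, correlated replicate effects
(blocks/plants), and any mechanistic ROS kinetics. Passing recovery tests
therefore demonstrates that the pipeline machinery works on data with the
assumed structure — not that real greenhouse data satisfy it.

## 5. NSGA-II and the reported optimum

The chromosome is (dose ∈ [0, 40] mM, day ∈ [14, 45] d, stress category)
— continuous dose/time (the reported optima are interior to the tested
levels) and a categorical stress gene. Population 50, 200 generations,
crossover 0.8, mutation 0.05 ('Atabaki') / 0.01 ('Rabab'). Two-point
crossover exchanges a contiguous segment of the 3-gene chromosome;
mutation perturbs continuous genes by a Gaussian with sd = 10% of the
gene's range (clipped to bounds) and resets the stress gene uniformly.
Environmental selection is the canonical elitist μ+λ: non-dominated
sorting, then crowding distance within the last admitted front.
Out-of-bounds children are clipped (the simplest feasibility repair).
Determinism under a fixed seed is property-tested.

**Ideal-point selection.** From the final front a single solution is
reported: the member minimising the Euclidean distance to the utopia
point (per-objective best over the front), after orienting all objectives
to "smaller is better" and normalising. `select_ideal_point()` offers two
normalisations. The textbook choice — min–max over the front — is the
default of the standalone function, but the pipeline normalises by the
traits' *training standard deviations* instead. The reason is a
measurable pathology: once the dose suppression of a damage marker has
saturated, its variation across the front is at replicate-noise level,
and min–max normalisation stretches that noise to a full unit of
distance; the enzyme-optimal front member is then always the *worst*
normalised member on that marker (every direction away from the optimum
improves it slightly), and the selected compromise wanders several mM
away, driven by noise. Fixed data-scale normalisation weights each
objective by how much it actually varies in the experiment, making the
selection stable across seeds. Both options remain available.

## 6. Pipeline, reproducibility and problem sizes

`run_pipeline()` chains generation (or CSV input) → encoding → split →
standardisation → per-family nested CV → comparison → surrogate bundle →
NSGA-II → report, per cultivar. Every stochastic stage receives a
sub-seed derived deterministically from the global seed and the stage
name, so reruns are bit-identical (hash-compared in the tests) and the
CSV and synthetic data paths produce identical downstream results.
Datasets are serialised with 17 significant digits so the CSV round trip
is bit-exact.

Problem sizes used by the test-suite benchmarks: 192-sample datasets
(the full factorial), five pipeline seeds for the recovery check, 100
random datasets/vectors for the kernel-limit and metric-identity
properties, and 100 random populations (n ≤ 40, m = 7) for the
non-dominated-sorting oracle.

## 7. Known limitations

- The surrogate's dose/time resolution is bounded by the factorial grid;
  with doses {0, 10, 20, 40} any kernel model localises the optimum only
  to a few mM (the worked example's 23 mM vs. a true 20 mM).
- GRNN predictions cannot leave the convex hull of the training targets,
  so extrapolation beyond observed trait ranges is structurally
  impossible (and intended).
- Model comparison uses a point estimate of test R²; no uncertainty is
  attached to the family ranking.
- The reported single optimum depends on the ideal-point rule; other
  defensible multi-criteria rules (knee points, reference directions)
  would pick different front members.
- NSGA-II hyperparameters are taken as given; no convergence diagnostics
  beyond the per-generation log are computed.
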