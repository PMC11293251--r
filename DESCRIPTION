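Package: gabaopt
Title: Surrogate Modelling and Multi-Objective Optimisation of GABA
    Stress-Mitigation Treatments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models physio-biochemical responses of plants to exogenous
    gamma-aminobutyric acid (GABA) under drought, salinity and combined
    stress with four surrogate regression families (generalized regression
    neural network, radial basis function network, random forest and
    epsilon-insensitive support vector regression), selects the best family
    by cross-validated R2/RMSE/MBE, and couples the winning surrogate to an
    NSGA-II multi-objective search that maximises five antioxidant and
    protein traits while minimising two oxidative-damage markers. Ships a
    synthetic factorial data generator with an analytically known optimum so
    that optimum recovery can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
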