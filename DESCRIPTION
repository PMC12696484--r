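Package: nanoqstr
Title: Quantitative Structure-Toxicity Modelling of Iron Carbide
    Nanoparticles from Atomistic Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds spherical iron carbide nanoparticles from CIF crystal
    unit cells, computes a 57-entry atomistic descriptor vector (geometry,
    coordination, bond-orientational order and pair-potential energy
    statistics over whole-particle, core and shell regions), fuses the
    descriptors with tabular dose-response viability data, and trains
    regression models of 24-hour cell viability under OECD-style QSAR
    validation: nested cross-validation over six algorithms,
    Golbraikh-Tropsha external-validation criteria, leave-one-out Q2,
    Y-scrambling and bootstrap confidence intervals. Predictions are gated
    by a distance-based applicability domain (Euclidean or weighted Gower)
    and explained with permutation-sampling Shapley attributions,
    permutation importance and partial-dependence/ICE machinery. Includes
    a synthetic-data module (toy CIFs and a simulated dose-response table)
    so the full workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    cluster,
    lightgbm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
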