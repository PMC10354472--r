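Package: nestwatch
Title: Within-Nest Behavioural and Thermal Analysis of Bumblebee Colonies
    Under Combined Pesticide and Cold Stress
Version: 0.1.0
Authors@R:
    person("Nestwatch", "Developers", email = "nestwatch@example.org",
           role = c("aut", "cre"))
Description: A pipeline for analysing tagged-bee trajectories and calibrated
    thermal imagery from bumblebee nests under combined neonicotinoid and
    cold stress. Provides readers and writers for trajectory tables, nest
    maps, probe logs and thermal stacks; a seeded synthetic colony and
    thermal-camera generator with recorded ground truth; per-frame thermal
    calibration against in-nest probes and smooth non-rigid registration of
    tracking coordinates into thermal frames; the eleven per-bee behavioural
    metrics, contact networks and on/off-nest classification; a PCA-based
    spatial-centrality score with Yeo-Johnson normalisation; body-temperature
    conditioned Markov activity-transition estimation with treatment-arm
    contrasts; mixed-effects behavioural models and a Poisson colony-growth
    model with AIC-based model selection; and a one-command orchestration of
    the whole analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
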