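Package: orchidflow
Title: Spatial Genetic Structure, Mating System and Paternity Analysis for
    Mapped Microsatellite Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete gene-flow analysis toolkit for spatially mapped,
    codominant microsatellite (SSR) plant populations: per-locus and
    per-cohort diversity statistics with Markov-chain exact Hardy-Weinberg
    tests and paternity exclusion probabilities; AMOVA differentiation with
    permutation significance and standardized G'st; univariate O-ring
    point-pattern analysis with Monte Carlo envelopes for complete spatial
    randomness; Loiselle kinship correlograms with the Sp statistic and a
    cubic residual-curvature test that separates seed-limited from
    pollen-limited dispersal; multilocus mixed-mating outcrossing estimation
    with correlated paternity and effective pollen-donor numbers; and
    likelihood (LOD) paternity assignment with simulation-calibrated
    confidence tiers. A spatially explicit forward simulator of clustered
    adults, dispersal kernels and single-donor progeny arrays makes every
    estimator verifiable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
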