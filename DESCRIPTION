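Package: quantnet
Title: Quantile-Graph Maps Between Time Series and Networks
Version: 0.1.0
Authors@R:
    person("quantnet", "developers", email = "quantnet@example.org",
           role = c("aut", "cre"))
Description: A forward map from a univariate time series to a weighted
    directed network (quantile discretization followed by first-order
    Markov transition estimation) together with an approximate inverse
    (row normalization, simulated-annealing seriation of the transition
    matrix, random-walk surrogate generation and uniform within-quantile
    emission). Includes the generators used to validate the round trip
    (a tunable periodic-to-random ensemble, Lorenz and Roessler
    trajectories, synthetic ring/modular/star networks), diagnostics
    (autocorrelation, periodogram, spectral slope, strengths,
    inverse-weight shortest paths, modularity with a shuffle null) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
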