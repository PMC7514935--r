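Package: bbconflict
Title: Prior-Data Conflict Detection for Beta-Binomial Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects prior-data conflict in conjugate Beta-Binomial models via
    two criteria: the Data Agreement Criterion (the ratio of the distance from a
    benchmark posterior to the expert prior over the distance to the benchmark
    prior, conflict when the ratio exceeds 1) and the prior-predictive surprise
    p-value of Nott and colleagues (the tail probability of the prior-to-posterior
    divergence under the expert's Beta-Binomial prior predictive, conflict at
    small p). Both criteria are generic over a registry of statistical distance
    measures (total variation, Hellinger, Kolmogorov, Euclidean, Manhattan,
    Sorensen, intersection, harmonic mean, Bhattacharyya, divergence, Jeffreys,
    Jensen-Shannon, Kullback-Leibler and the Renyi family) evaluated on
    discretized densities over the unit interval. Includes a simulation-study
    harness that sweeps expert-prior location and concentration grids and
    replicate binomial samples to compare how lenient or stringent each distance
    measure makes each criterion, with tidy tabular results, ggplot2 figures and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
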