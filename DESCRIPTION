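Package: wmpopdyn
Title: Population Dynamics of Working-Memory Activity in Prefrontal Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for single-neuron and population-level working-memory
    dynamics in delayed-response tasks with an intervening reward cue. Implements
    intrinsic-timescale estimation from fixation-period spike-count autocorrelation,
    pseudopopulation decoding by linear discriminant analysis (within-time,
    cross-temporal, cross-task, and error-trial variants), correlation-based
    pairwise-difference discriminability with cluster-based permutation inference,
    mnemonic-subspace geometry and stimulus-variance timecourses, and sliding
    single-neuron selectivity statistics. Ships a task-structured synthetic
    spike-train generator (Ornstein-Uhlenbeck modulated Poisson) with known ground
    truth so every stage of the pipeline can be validated end to end.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
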