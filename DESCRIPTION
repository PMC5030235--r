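Package: spikedrift
Title: Self-Organized Dynamical States in Excitatory Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of autonomous networks of conductance-based
    excitatory integrate-and-fire neurons with distributed afferent coupling
    strengths. Provides a fast fixed-timestep simulator with refractory
    dynamics, the analytic stationary mean-field solution for asynchronous
    drifting states, automatic classification of self-organized dynamical
    states (inactive, drifting, synchronized and mixed), interspike-interval
    statistics, and a chaos diagnostic based on the return map of consecutive
    interspike intervals and its box-counting fractal dimension.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    pracma,
    readr,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
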