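Package: pulseFRET
Title: Bayesian Nonparametric Inference for Pulsed-Illumination Single-Photon
    smFRET Traces
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses single-molecule FRET photon traces recorded
    under pulsed illumination. Photon arrivals are modelled pulse by pulse: a
    hidden discrete-time Markov chain over conformational (system) states
    modulates the FRET rate, and each laser pulse yields at most one detected
    photon per channel with an arrival delay (microtime) distributed as an
    exponential decay convolved with a Gaussian instrument response, subject to
    crosstalk, detection losses, and background. Inference is by Markov chain
    Monte Carlo: forward-filtering backward-sampling of the state trajectory
    with empty-pulse grouping, conjugate Dirichlet updates for the transition
    matrix, and Metropolis-Hastings updates for photophysical rates. A
    truncated hierarchical-Dirichlet-process prior over transition rows turns
    the sampler into an infinite hidden Markov model that learns the number of
    system states together with transition probabilities, FRET efficiencies,
    fluorophore lifetimes, and per-state escape rates.
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    MASS,
    data.table,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
biocViews: Bayesian, SingleMolecule, TimeCourse, HiddenMarkovModel
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
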