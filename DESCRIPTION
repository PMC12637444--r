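Package: erpnet
Title: Rate-Network Models of Oddball Event-Related Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hierarchical excitatory-inhibitory rate networks with
    short-term synaptic depression (STD) on input and feedback synapses to
    model mismatch negativity (MMN) and P300-like responses in passive and
    active auditory oddball paradigms. Provides oddball stimulus generation,
    seeded network instantiation with spectral-radius and E/I-balance
    constrained random weights, forward-Euler integration of one- and
    two-region models, FORCE/recursive-least-squares training of a behavioral
    readout with depressing feedback, and the accompanying analysis stack:
    trial-aligned difference traces and peak latencies, probability and
    interstimulus-interval sweeps, frontal amplification ratios,
    condition-concatenated PCA with conic ellipse fitting of population
    trajectories, and sliding-window linear decoding under observation noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
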