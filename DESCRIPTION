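Package: lnkadapt
Title: Two-Pathway Linear-Nonlinear-Kinetic Models of Retinal Contrast Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, estimation and analysis tools for studying how
    adaptive changes in retinal temporal bandwidth arise from parallel On and
    Off pathways with different synaptic thresholds. Implements the
    linear-nonlinear-kinetic (LNK) cascade -- a temporal filter, a sigmoidal
    synaptic nonlinearity, and a four-state first-order kinetic model of
    vesicle release -- for one or two weighted pathways, together with
    Gaussian-flicker stimulus generation, reverse-correlation LN model
    estimation, adaptation metrics (gain, delay, offset, median temporal
    frequency), pathway decomposition and component-exchange analyses, and
    constrained model fitting with interleaved k-fold cross-validation. A
    synthetic-data module generates ground-truth cells and noisy recordings so
    every analysis stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    yaml
Config/testthat/edition: 3
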