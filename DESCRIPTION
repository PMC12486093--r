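Package: dastdp
Title: Dopamine-Modulated Spike-Timing-Dependent Plasticity: Simulation and
    Mean-Field Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation and mean-field analysis of three
    dopamine-modulated spike-timing-dependent plasticity (STDP) rules
    (additive, symmetric, corticostriatal) at corticostriatal synapses onto
    D1-receptor spiny projection neurons.  Implements linear Poisson neurons,
    paired eligibility traces, reward-prediction-error dopamine signalling,
    and two reinforcement-learning task environments: two-channel action
    selection and single-channel value estimation.  Provides the averaged
    (mean-field) weight-drift systems for both settings, closed-form
    equilibria and stability thresholds, numerical equilibrium search with
    Jacobian classification, Monte-Carlo single-release drift probes, and
    orchestration of figure-level experiments (phase portraits, contingency
    switching, delay sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
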