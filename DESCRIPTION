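Package: synquant
Title: Quantal Analysis of Inhibitory Synaptic Transmission
Version: 0.1.0
Authors@R: person("synquant", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantal analysis of evoked and spontaneous
    inhibitory postsynaptic currents (IPSCs) recorded in voltage clamp:
    template-matching detection of miniature events, unitary IPSC
    statistics (amplitude, failures, CV, skewness, latency jitter),
    regularized Fourier deconvolution of release rates, parametric
    estimation of the time course of release by convolution fitting,
    readily-releasable-pool and replenishment analysis by
    cumulative-amplitude back-extrapolation and nonstationary
    fluctuation analysis, recovery-from-depression kinetics, and
    feedforward-inhibition conductance measures.  Includes a synthetic
    synapse generator (binomial release from a depleting/replenishing
    vesicle pool with parametric release-time distributions,
    asynchronous and spontaneous release, and band-limited noise) so
    that every estimator can be validated by parameter recovery against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
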