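Package: spikeburst
Title: Integrated Information Analysis of the Spiking-Bursting Stochastic Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact probability tables, closed-form and asymptotic
    "whole minus sum" integrated information, decoder-based mismatched
    information (phi-star), sign-transition thresholds, a seeded simulator
    and empirical plug-in estimation for a discrete-time, discrete-state
    spiking-bursting stochastic model of coordinated network bursting, as
    found in neuron-astrocyte networks. The model combines a system-wide,
    time-correlated two-state (spiking/bursting) component with
    time-uncorrelated per-node spontaneous spiking, and admits closed-form
    expressions for time-delayed mutual information and effective
    information over bipartitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
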