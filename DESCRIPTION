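Package: stdplif
Title: Optimal Spike-Pattern Detection with Leaky Integrate-and-Fire
    Coincidence Detectors and STDP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how a single leaky integrate-and-fire (LIF)
    neuron can detect a repeating spatiotemporal spike pattern embedded in
    Poisson background activity. Provides seeded generators for frozen-noise
    spike patterns and jittered presentation sessions, a closed-form
    signal-to-noise ratio (SNR) for coincidence detectors wired by
    spike-count selection strategies, constrained numerical optimization of
    the SNR over the strategy number, membrane time constant and integration
    window, fast clock-based LIF simulation for validating the theory, and
    an additive spike-timing-dependent plasticity (STDP) learning simulation
    with a presynaptic-trace LTP rule and homeostatic depression, together
    with an optimality classifier for the learned synaptic weights. All
    user-facing functions return tibbles and compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
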