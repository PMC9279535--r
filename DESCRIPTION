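Package: assrnet
Title: Steady-State Responses in Spiking Networks with Log-Normal Synaptic Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of steady-state evoked responses in
    conductance-based leaky integrate-and-fire networks whose
    excitatory-to-excitatory synaptic amplitudes follow a truncated
    log-normal distribution. Builds random directed networks with
    class-dependent coupling probabilities, conduction delays and
    amplitude-dependent stochastic transmission failure; drives them with a
    periodic windowed-Poisson stimulus; and quantifies stimulus entrainment
    of the excitatory population rate by power spectral density and
    inter-trial phase coherence across excitatory/inhibitory population
    ratios, with or without strong (> 9 mV) synapses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
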