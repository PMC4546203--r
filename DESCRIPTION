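Package: motifstdp
Title: Self-Consistent Theory of Spike-Timing-Dependent Plasticity and
    Motif Dynamics in Recurrent Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how pair-based, additive Hebbian
    spike-timing-dependent plasticity (STDP) shapes the wiring of recurrent
    networks of exponential integrate-and-fire (EIF) neurons. Provides a
    ground-truth stochastic network simulator with online STDP; Fokker-Planck
    threshold-integration numerics for stationary rates, linear response
    functions and spike-train power spectra; linear-response theory for
    network spike-train cross-covariances (full matrix solve and the
    length-one-path truncation); the self-consistent slow evolution of
    synaptic weights driven by spiking covariance; and a closed
    low-dimensional ODE system for the plasticity of two-synapse connectivity
    motifs (divergent, convergent, chain, recurrent-loop and open-chain),
    including fixed-point and separatrix analysis for balanced STDP rules.
    Network generators cover Erdos-Renyi graphs and digraphs with correlated,
    truncated power-law degree distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
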