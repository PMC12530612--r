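Package: scsurround
Title: Center-Surround Suppression in a Collicular Spiking Network Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a conductance-based leaky integrate-and-fire network
    of the superficial superior colliculus on a toroidal grid with
    distance-dependent Gaussian connectivity and PSP-amplitude-calibrated
    alpha synapses, and provides the center/surround stimulation protocols
    and recurrent-weight experiments used to study surround suppression.
    Also implements the companion slice-electrophysiology analyses on
    synthetic data: linear decomposition of voltage-clamp currents into
    excitatory and inhibitory synaptic conductances, peak and latency
    summaries with suppression classification, and threshold-based
    excitation-zone mapping from grid-scan EPSC amplitude maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
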