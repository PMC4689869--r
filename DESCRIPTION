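Package: mliplast
Title: Simulation of Plasticity at Parallel Fiber to Molecular Layer Interneuron Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based leaky integrate-and-fire model of a cerebellar
    molecular layer interneuron (MLI) driven by parallel fiber (PF) inputs, with
    double-exponential AMPA and voltage-dependent (magnesium-blocked) NMDA
    conductances, normalized spike-activity traces, and a gated steepest descent
    plasticity rule in which presynaptic activity gates the weight update and a
    scaled copy of the weight acts as a dynamic threshold. Includes a registry of
    ten in silico electrophysiology protocols (burst and continuous Poisson PF
    stimulation, voltage clamp, current clamp, threshold-scale modulation),
    current-injection calibration, trial-wise weight-change summaries, and
    LTP/LTD outcome classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
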