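Package: dendplast
Title: Dendritic-Spike Mediated Synaptic Plasticity in Reduced
    Multicompartment Spiking Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates reduced multicompartment pyramidal neurons (an
    exponential integrate-and-fire soma with adaptive threshold, electrically
    coupled to proximal and distal basal-dendrite compartments) with
    conductance-based AMPA/NMDA synapses and a local voltage-dependent
    plasticity rule combining spike-timing-dependent plasticity with
    NMDA-spike-gated dendritic long-term potentiation. Provides seeded
    stimulation protocols at the single-synapse, single-cell and recurrent
    network level (pairing, rate-dependent potentiation, temporal-order
    connectivity, associative feature networks and overlapping-memory
    retention), tidy accessors and plots for the recorded weight
    trajectories and spike rasters, and a multiplicity-weighted re-analysis
    of published connection-distance data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
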