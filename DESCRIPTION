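Package: lamstate
Title: Laminar and Behavioral-State Analysis of Auditory Cortical Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for extracellular recordings from auditory
    cortex during locomotion and optogenetic manipulation of inhibitory
    interneurons. Assigns cortical depths and layers to sorted units via
    current-source-density analysis of the stimulus-evoked local field
    potential, classifies trials as running or sitting from a smoothed
    running-speed trace, classifies units as narrow- or regular-spiking
    from spike waveforms, computes sound modulation indices under the four
    state-by-laser conditions, decomposes running and laser effects with a
    linear-additivity (interaction) test including matched trial
    subsampling, and measures the coupling between population firing and
    running speed with a shuffle-corrected distance correlation across time
    bin sizes. A calibrated synthetic-session generator with known ground
    truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
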