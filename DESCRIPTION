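Package: thetagamma
Title: Theta-Gamma Cross-Frequency Coupling and Spike Phase-Locking Analysis
    for Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for local field potential (LFP) and spike
    recordings under urethane anesthesia: complex Morlet wavelet
    time-frequency decomposition with reference-band power normalization,
    theta/slow-wave brain-state segmentation, zero-phase FIR bandpass
    filtering, theta-cycle and gamma-episode detection, theta-gamma
    cross-frequency coupling via circular resultant vectors, spike waveform
    classification and spike-LFP phase locking with Rayleigh testing, and
    group statistics (Mann-Whitney U, Benjamini-Hochberg FDR, simulation
    based power analysis). Includes a seeded synthetic-session generator so
    that every stage is verifiable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
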