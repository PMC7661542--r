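Package: pelletmass
Title: Single-Pellet Dissolution Profiling with Vibrating-Tube Buoyant-Mass Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the dissolution of single controlled-release
    drug pellets from vibrating glass-tube resonator data. Provides a forward
    simulator of resonance-frequency traces (buoyant-mass physics, transit
    peak pairs, noise and drift), zero-phase low-pass filtering, baseline
    estimation, transit peak-pair detection, bulk-density and point-mass
    calibration with a mass-resolution estimate, conversion of peak heights
    to calibrated buoyant-mass time series, and piecewise-linear dissolution
    profiling with abrupt-jump detection and summary metrics (starting mass,
    insoluble "ghost" residue, onset and completion times). All pipeline
    functions take and return tibbles so analyses compose with the pipe.
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
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
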