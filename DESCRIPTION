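Package: thztds
Title: Terahertz Time-Domain Spectroscopy of Glass Transitions in Amorphous Polymers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing variable-temperature terahertz time-domain
    spectroscopy (THz-TDS) of amorphous pharmaceutical materials. Converts
    time-domain electric-field waveforms into frequency-dependent optical
    constants (refractive index and absorption coefficient) via the
    transfer-function method with phase unwrapping and Fabry-Perot echo
    gating, assembles the temperature dependence of the absorption
    coefficient at 1 THz, and locates the two glass-transition temperatures
    (the beta-relaxation onset Tg_beta and the alpha-relaxation onset
    Tg_alpha) as intersections of piecewise linear fits found by exhaustive
    least-squares segmentation. Includes a physics-based synthetic waveform
    generator (single-cycle pulses, slab transmission through free-standing
    or quartz-windowed geometries) so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
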