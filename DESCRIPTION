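Package: afomtools
Title: Excitation-Emission Matrix Processing and Per-Cell Fluorescence for
    Microbial AFOM Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying aquatic fluorescent organic matter (AFOM)
    produced by bacterial cultures in low-fluorescence simulated freshwater.
    Implements excitation-emission matrix (EEM) preprocessing (blank
    subtraction, inner-filter-effect correction, Rayleigh scatter masking,
    spectral cropping, quinine sulfate unit normalization), Coble-style
    peak picking (Peaks T, C, C+, B, M) with time-course extraction,
    viable-count growth-curve handling with lag/exponential/stationary
    phase classification, enumeration-corrected per-cell fluorescence
    (QSU per 10^6 CFU), per-condition summary tables, and a seeded forward
    simulator that generates EEM time series and growth curves so the whole
    pipeline is exercisable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'afomtools-package.R'
    'eem-model.R'
    'peaks.R'
    'eem-io.R'
    'growth.R'
    'summary.R'
    'preprocess.R'
    'simulate.R'
    'cli.R'
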