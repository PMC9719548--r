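Package: ssfm
Title: Spectral-Shift Fluorescence Microscopy Image Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Processing pipeline for spectral-shift fluorescence microscopy
    (SSFM) of rhodamine-6G stained skin tissue. Converts raster-scanned
    per-pixel fluorescence spectra into co-registered intensity,
    peak-emission-wavelength and fluorophore-concentration micrographs,
    classifies pixels into tissue classes (melanoma, BCC, SCC, normal,
    nevus) by spectral band, and renders false-color images. Includes a
    forward simulator of the instrument (class-specific Gaussian emission
    lineshapes, concentration-dependent intensity with quenching, Gaussian
    or Rician noise, dichroic cutoff) so every stage is testable at desk
    scale, plus readers and writers for long-format CSV and hierarchical
    JSON spectral-cube containers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    pracma,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
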