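Package: fcvolume
Title: Batch Analysis of Atomic Force Microscopy Force-Volume Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reads grids of plain-text atomic force microscopy (AFM) force
    curves, converts cantilever deflection to force, subtracts the zero-force
    baseline, locates the tip-sample contact point by three selectable
    routines, and reconstructs calibrated topography, stiffness and Young's
    modulus maps from the contact region of every curve.  Young's moduli are
    obtained from the slope of force versus squared indentation depth under
    the Sneddon cone / Bilodeau pyramid contact model, optionally over several
    depth windows ("force tomography").  A seeded synthetic force-volume
    generator with known modulus and height fields supports end-to-end
    validation, and maps are exported as labelled text matrices importable by
    Gwyddion and as PNG images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
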