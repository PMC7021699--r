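Package: porescope
Title: Membrane Pore Sizing from Dextran Size-Exclusion Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cell-membrane permeabilization and cell-wall
    permeability of walled microalgae (Chlamydomonas reinhardtii) from
    multi-channel confocal fluorescence images of FITC-dextran uptake.
    Provides Flory coil-radius calculations for a dextran probe ladder,
    cell segmentation from a wall-stain channel, partitioning of each
    cell interior into ten equal-area concentric zones, background-
    normalized radial intensity profiles, and interval estimation of
    membrane pore radius from probe penetration calls. Includes a seeded
    generator of synthetic confocal-like scenes with ground truth for
    validation, so the full pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
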