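Package: endovesiq
Title: Object-Based Vesicle Colocalization Analysis for Endothelial Shear-Stress Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies marker co-occurrence in endocytic vesicles from
    multi-channel fluorescence micrographs of endothelial cells exposed to
    laminar shear stress. Detects Caveolin-1 (or EEA1) puncta by top-hat
    background subtraction, automatic thresholding and connected-component
    particle analysis; classifies each vesicle as secondary-marker positive
    when its mean intensity is at least a configurable fraction (default 15%)
    above the whole-image mean of that channel; screens co-positive vesicles
    for further markers (EEA1, SMAD1); extracts multi-channel line profiles;
    and compares per-field vesicle counts between conditions (e.g. low vs
    high shear stress). Includes a seeded synthetic-micrograph generator with
    vesicle-level ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
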