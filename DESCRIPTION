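Package: hemomorph
Title: Morphometry of Intracerebral Hematoma Change on Paired CT Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies morphological change of intracerebral hematomas
    between paired, co-registered CT segmentations: volume, iso-surface
    area and the surface regularity (sphericity) index; axis-aligned
    diameters measured on maximum-area slices and longitudinal-axis
    typing; diameter length and direction change; geometric-centre
    movement; hematoma-expansion classification and Dice-based
    registration quality control; cohort-level summaries with subgroup
    tests and region-wise synthesis of movement directions; and a
    prognostic logistic model for poor outcome with discrimination and
    calibration diagnostics. Ships a seeded generator of paired synthetic
    hematoma masks with analytic ground truth so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    pROC,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
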