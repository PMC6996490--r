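Package: axentry
Title: Quantification of Actin-Based Invasion in Regenerating Sensory Axons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to quantify spinal re-entry of regenerating dorsal-root-
    ganglion (DRG) axons from growth-cone time-lapse traces: detection of
    transient growth-cone actin concentrates (intensity peaks) and their
    durations, three-state classification of growth-cone actin organization,
    growth-cone velocity during concentrates, retraction and spinal re-entry
    calling against the glia limitans, and scoring of larval hypothermic
    shiver behavior. A condition-preset stochastic generator produces
    synthetic axon traces, raster movies, tail-kinematics series and
    animal-level records with ground truth, so every estimator can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    jsonlite,
    yaml,
    withr,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
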