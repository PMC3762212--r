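Package: synmorph
Title: Synaptic Vesicle Pool Morphometry from Serial-Section EM Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of annotated serial-section electron
    micrographs of presynaptic terminals captured by time-resolved
    (flash-and-freeze) fixation. Classifies vesicles into docked, tethered,
    30-nm and cytoplasmic pools and endocytic structures by site; computes
    3D distances to the dense projection, binned distance distributions and
    normalized per-profile/per-synapse counts; fits exponential
    recovery/decay kinetics for pool refilling, paired-pulse recovery and
    pit resolution; runs an exocytosis/endocytosis membrane-area budget in
    synaptic-vesicle equivalents; and fits Gaussian mixtures to large-vesicle
    diameter histograms with AIC model selection. A seeded synthetic
    annotation generator emulating the study conditions makes every analysis
    testable without raw micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    readr,
    stats,
    minpack.lm,
    generics,
    ggplot2,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
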