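Package: cpscan
Title: Label-Free Carbon Particle Quantification and Fetoplacental Study Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying combustion-derived carbon particles in
    two-channel femtosecond-laser tile scans of placental and fetal tissue and
    for the downstream hierarchical exposure study analysis. Particles are
    called by dual-channel fractional-of-maximum thresholding and
    connected-component labelling of the cross-channel intersection, converted
    to volumetric loads (particles per cubic millimetre) via automated tissue
    segmentation and the known section thickness, pooled per litter, and
    analysed with exact small-sample nonparametric tests, linear mixed-effects
    biometry models and a from-scratch multiple factor analysis. A synthetic
    study generator renders two-channel images with a known ground truth so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    nlme,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph,
    withr
Config/testthat/edition: 3
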