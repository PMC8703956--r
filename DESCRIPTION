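Package: tracerseg
Title: Tracer-Aware Lesion Segmentation for Breast DCE-MRI
Version: 0.1.0
Authors@R:
    person("tracerseg", "developers", email = "tracerseg@example.org",
           role = c("aut", "cre"))
Description: A pipelined, tracer-aware toolkit for lesion segmentation in
    bilateral breast dynamic contrast-enhanced MRI (DCE-MRI). The pipeline
    covers breast masking with weighted multi-planar fusion, intensity-based
    motion correction of post-contrast series, three-time-point (3TP) slice
    encoding of the contrast-agent kinetics, a modified U-Net trained with a
    Dice loss, and a chunked "eras/epochs" training scheduler that balances
    lesion against healthy slices. A seeded 4D phantom generator with known
    breast and lesion masks supports end-to-end validation, together with a
    patient-wise cross-validation and evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
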