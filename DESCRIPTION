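Package: irv4d
Title: Contour Propagation, Consensus and Internal Organ-at-Risk Volumes
    for Respiratory-Correlated 4D MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to evaluate deformable-image-registration (DIR) propagated
    organ-at-risk contours on respiratory-correlated (amplitude-binned) 4D MRI.
    Provides a seedable synthetic 4D respiratory phantom with analytic
    ground-truth organ masks and displacement fields, simulated human raters
    and surrogate mis-binning artifacts; a free-form intensity-based
    multi-resolution DIR solver with energy-descent iterations; binary STAPLE
    expectation-maximization consensus with S95 thresholding;
    Jaccard/sensitivity/specificity overlap metrics with intra- and
    inter-observer variability statistics; and construction of the internal
    organ-at-risk volume (IRV) as the Boolean union of per-phase contours,
    orchestrated end-to-end as a multi-subject synthetic study.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    withr,
    rlang,
    generics,
    tibble,
    dplyr,
    tidyr,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
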