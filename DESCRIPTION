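Package: hbimage
Title: Non-Invasive Hemoglobin Estimation from Eyelid and Fingernail
    Photographs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating blood hemoglobin concentration from the
    color of melanocyte-free tissue (palpebral conjunctiva and nail bed)
    in standard RGB photographs. Provides a synthetic-study generator
    (cohort, quality-of-life scores, clinician triage labels, rendered
    image patches with known ground truth), region-of-interest refinement
    by iterative mask erosion and Hough-circle lower-arc isolation,
    hue-histogram and principal-component feature engineering, ridge and
    gradient-boosted-tree predictors, patient-grouped cross-validation
    with median aggregation, and a deterministic corridor decision layer
    that combines predicted hemoglobin with patient-reported outcome
    strata by equal-weight majority vote.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
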