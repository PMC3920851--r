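Package: hipwear
Title: Polyethylene Liner Wear Measurement in Total Hip Arthroplasty from CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers polyethylene liner wear in total hip arthroplasty from a
    computed tomography volume by measuring the separation between the
    acetabular-cup and femoral-head centers. Seven operator landmarks and an
    intensity threshold constrain a ray-cast surface search for the outer cup
    hemisphere and the head sphere; each surface is fitted by a robust
    random-circumsphere procedure with histogram initialisation and two-stage
    outlier pruning, and wear is summarised with regression against the
    identity line, summary statistics and a repeatability coefficient.
    Includes a synthetic voxel-phantom generator with known ground truth for
    validating the full pipeline at sub-voxel displacements.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    optparse,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
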