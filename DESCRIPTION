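Package: dirval
Title: Hybrid Deformable Image Registration with Controlling Structures and Points
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating hybrid deformable image
    registration (DIR) strategies for MR-guided adaptive radiotherapy of the
    pelvis. Provides a seeded synthetic pelvic phantom (prostate-analog CTV,
    bladder, rectum) with ground-truth deformations including bladder volume
    doubling; fixed-topology surface-mesh correspondence and geodesically
    separated controlling-point selection; a multi-resolution deformable
    registration supporting intensity-only, controlling-structure (CS) and
    controlling-structure-plus-points (CS+P) strategies; geometric contour
    agreement metrics (Dice, mean and maximum distance to agreement); and
    dose-volume-histogram difference analysis with clinical metrics (CTV D98%,
    bladder D5cc, rectum D1cc) and cohort percentile bands.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
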