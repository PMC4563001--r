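Package: cathreg
Title: Catheter-Based 2D/3D Rigid Registration for Continuous Vascular
    Roadmapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers a 3D arterial centerline tree to the 2D catheter
    centerline visible in single-plane fluoroscopy, enabling a continuously
    updated vascular roadmap during abdominal catheter interventions.
    Candidate vessel paths are ranked by a tangent-based shape similarity to
    the catheter, then rigidly registered (three rotations plus two
    detector-plane translations) under a cone-beam projection model with a
    multi-resolution brute-force optimizer or a two-stage Powell optimizer.
    Includes a synthetic generator for hepatic-artery-like trees and
    simulated catheters, the tip-error and paired-vessel evaluation metrics,
    and a parameter sweep harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
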