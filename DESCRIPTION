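Package: printqa
Title: Error Propagation Along the Medical 3D-Printing Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and metrology of the medical 3D-printing
    chain. Generates a femur-like phantom, simulates CT acquisition (slice
    thickness, reconstruction kernel, noise), threshold segmentation with
    sub-voxel iso-surfacing, digital smoothing profiles, and fused-filament
    printing (layer staircase and bed-adhesion warping). Quantifies the
    surface deviation contributed by each stage - segmentation error,
    digital editing error and printing error - with a rigid ICP alignment
    and signed surface-deviation engine, and combines the partial errors
    into a total error by Gaussian error propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
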