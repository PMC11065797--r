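Package: sparsect
Title: Sparse-View CT Simulation, Residual U-Net Artifact Correction, and
    Reader-Study Analytics
Version: 0.1.0
Authors@R: person("sparsect", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates sparse-view computed tomography from full-view
    chest-CT-like phantom slices (parallel-beam Radon transform and
    ramp-filtered backprojection), corrects streak artifacts with a
    residual dual-frame U-Net implemented natively (backpropagation and
    Adam in compiled code), and evaluates the result with MSE/SSIM image
    quality metrics, Dice overlap, confusion-matrix diagnostics, and the
    clustered Wilcoxon signed-rank test for multireader studies. Includes
    a seeded synthetic phantom and reader-annotation generator so the full
    pipeline runs without patient data.
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
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
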