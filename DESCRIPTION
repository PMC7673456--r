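Package: glucest
Title: Glutamate-Weighted CEST MRI Analysis with a Bloch-McConnell Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of glutamate-weighted chemical exchange
    saturation transfer (GluCEST) MRI studies: assembly of voxel-wise
    Z-spectra from saturation image stacks, voxel-by-voxel B0 realignment,
    MTR-asymmetry contrast at +/-3 ppm, dual-echo B0 and double-angle B1
    field mapping, mono-exponential T1 (inversion recovery) and T2
    (multi-echo) relaxometry, ROI group statistics (pooled t-tests, one-way
    ANOVA with Bonferroni post-hoc), and home-cage activity normalization.
    Includes a seeded Bloch-McConnell multi-pool simulator that generates
    complete two-group synthetic studies with known ground truth, so the
    whole pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    minpack.lm,
    EBImage,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
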