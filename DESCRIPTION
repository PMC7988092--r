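Package: qamr
Title: Volumetric Quantitative Ablation Margins from Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes volumetric quantitative ablation margins (QAM) for
    thermal ablation of liver tumors from co-registered binary segmentation
    masks (NIfTI). Signed exact Euclidean surface distances are measured from
    every tumor-surface voxel to the ablation zone, with an exclusion
    algorithm for subcapsular tumors lying within a configurable distance of
    the liver capsule. Margin distributions are summarized as percentiles,
    traffic-light coverage classes and 1 mm substrata histograms, and can be
    projected onto the ablation surface for 3-D review. Sphere-based phantom
    cases are generated programmatically for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
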