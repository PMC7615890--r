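Package: laminae
Title: Voxel-Space Layer and Column Analysis for Laminar fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for depth-dependent (laminar) fMRI analysis that operate
    directly on the voxel lattice of NIfTI images, without surface meshes,
    topology requirements or anatomical reference volumes. Implements
    equi-distant and equi-volume cortical depth estimation from an
    integer-coded rim segmentation, unit-column construction with curvature
    classification, landmark-based columnar distances and volumetric
    flattening, layer-restricted and intensity-gradient-weighted spatial
    smoothing with kissing-gyri protection, quality-assessment maps for
    thermal-noise-dominated time series (tSNR, skew, kurtosis,
    autocorrelation, global-signal correlation) plus a full 3D noise kernel,
    VASO blood-nulled/BOLD interleave splitting with dynamic-division BOLD
    correction, and model-based draining-vein mitigation (linear-offset,
    scaling and leakage models). Deterministic phantom generators provide
    analytic ground truth for every algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
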