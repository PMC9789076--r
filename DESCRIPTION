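Package: lamcrib
Title: 3D OCT Segmentation and Lamina Cribrosa Defect Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orthogonal-plane analysis of 3D optical coherence tomography
    (OCT) volumes of the optic nerve head for detecting lamina cribrosa
    defects (LCDs): synthetic optic-nerve-head phantom generation with known
    ground truth, slice extraction and reassembly along the axial, sagittal
    and coronal planes, simulation of sparse manual annotation, per-plane 2D
    semantic segmentation (a deterministic intensity/geometry baseline and a
    small trainable convolutional encoder-decoder), per-voxel majority-vote
    fusion of the three plane-wise predictions, morphological detection and
    localization of full-thickness gaps between the lamina cribrosa and the
    peripapillary sclera, cohort-level evaluation, and export of surface
    meshes and en-face overlay images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    tiff,
    RNifti,
    png,
    yaml,
    jsonlite,
    withr,
    EBImage,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
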