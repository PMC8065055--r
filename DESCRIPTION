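Package: trackfuse
Title: Tracker-Based Multimodal Image Fusion for Ultrasound-Guided Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a hybrid navigation pipeline that fuses a pre-procedure
    volumetric modality (MR) with intra-procedure 3D ultrasound by replacing
    inter-modal image registration with tracked-device calibration chains plus a
    single intra-modal US/US registration. Provides homogeneous transform algebra
    between named coordinate frames, paired-point rigid registration with fiducial
    and target registration error statistics, stylus pivot and probe/MR gantry
    calibrations, table-shift compensation, transform-chain fusion, masked affine
    registration with a Mattes-style mutual-information metric, segmentation
    overlap metrics (Dice, Hausdorff, mean boundary distance, PSNR), synthetic
    calibration and prostate phantoms with tracker-jitter simulation, and
    Monte-Carlo propagation of fiducial localization errors through the full
    transform chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
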