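Package: vmsbr
Title: Volume-, Motion- and SBR-Adaptive Threshold Segmentation of PET
    Internal Target Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Delineation of the internal target volume (motion envelope) of
    moving lung tumors on FDG-PET by adaptive activity-concentration
    thresholding.  Implements the VMSBR model, an analytical function mapping
    tumor volume, respiratory motion extent and source-to-background ratio to
    the optimal segmentation threshold, together with the recovery-coefficient
    correction for partial-volume and motion degradation of measured SBR, six
    comparator thresholding methods from the literature, seed-based 3D region
    growing, a moving-sphere phantom simulator for calibration and validation,
    mesh-based surface-separation metrics, model refitting by ordinary least
    squares, and paired cohort comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
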