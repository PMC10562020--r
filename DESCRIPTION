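Package: cordcascade
Title: Cascaded Axial-Sagittal Attention U-Net Segmentation of the Injured
    Spinal Cord
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-plane cascaded segmentation of the spinal cord from sagittal
    T2-weighted MRI. An attention-gated U-Net first segments axial slices
    cropped around the cord centerline; the axial segmentations are rearranged
    sagittally and, together with the corridor-masked sagittal intensities,
    feed a second attention-gated U-Net that produces the final mask. Includes
    NIfTI reorientation and anisotropic resampling, paired elastic-deformation
    and rotation augmentation with scheduled renewal, Dice-loss training with
    Adam, patient-grouped K-fold planning with paired t-test comparison, the
    four standard overlap and surface-distance metrics, and a synthetic
    phantom generator emulating traumatically injured cords so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
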