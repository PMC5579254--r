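Package: boldvar
Title: BOLD Signal Variability Under Vascular Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise analysis of moment-to-moment BOLD signal variability
    (SD_BOLD) during fixation and its relation to age group after statistical
    control of vascular factors. Implements dual-echo BOLD/pCASL signal
    separation (surround subtraction and addition), criteria-based
    independent-component denoising, block-normalized SD_BOLD computation,
    hypercapnia GLM estimation of cerebrovascular reactivity (CVR), absolute
    cerebral blood flow (CBF) quantification from pseudo-continuous arterial
    spin labeling, calibrated-fMRI estimation of the maximum BOLD signal
    change (M), Task partial least squares with permutation and bootstrap
    inference, and a regression suite with outlier handling and bootstrap
    confidence intervals. A synthetic-cohort generator with known ground
    truth exercises every stage end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    signal,
    car,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
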