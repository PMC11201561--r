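Package: nodulegp
Title: Adversarial Growth Prediction of Lung Nodules in Follow-Up Low-Dose CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the one-year follow-up appearance of a screening-detected
    lung nodule from its baseline low-dose CT image patch with a Wasserstein
    generative adversarial network trained under a composite synthesis loss
    (L1 + structural similarity + learned perceptual + adversarial) and a
    gradient-penalty critic. Includes a synthetic nodule-growth simulator
    driven by volume doubling times, CT patch preparation utilities
    (isotropic spline resampling, ROI extraction, intensity windowing), and
    the downstream risk-stratification statistics: ROC/AUC with DeLong
    comparison, Hochberg correction, reclassification tables, and the net
    reclassification index with Z-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pROC,
    RNifti,
    png,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
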