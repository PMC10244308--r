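Package: anodiff
Title: Anomaly Detection in Longitudinal Difference Volumes from Breast MRI Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects anomalous inter-visit appearance change in longitudinal
    volumetric screening images and associates it with future lesion emergence.
    Provides a synthetic longitudinal cohort generator, preprocessing of visit
    series into registered masked difference volumes and labeled 2-D patches, a
    generative adversarial anomaly model (Wasserstein GAN with gradient penalty
    plus an encoder) trained on normal inter-visit change, sliding-window
    anomaly maps with examination-level scores, and statistical evaluation via
    bootstrapped ROC curves with Youden thresholds and logistic regression with
    a scanner covariate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    RNifti,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
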