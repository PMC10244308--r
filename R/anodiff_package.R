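#' anodiff: anomaly detection in longitudinal screening difference volumes
#'
#' Detects anomalous inter-visit appearance change in longitudinal volumetric
#' screening images and associates it with future lesion emergence. The
#' analysis chain is: synthetic cohort generation (or real volumes with the
#' same manifest schema), registration and breast segmentation, inter-visit
#' difference volumes of consecutive grade-1 visits, 64x64 patch extraction
#' with a background-exclusion rule, a Wasserstein-GAN-plus-encoder anomaly
#' model of normal change, sliding-window anomaly maps with examination-level
#' scores, and evaluation by bootstrapped ROC curves (Youden thresholds) and
#' logistic regression with a scanner covariate.
#'
#' @keywords internal
"_PACKAGE"
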