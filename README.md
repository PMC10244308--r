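# anodiff

Anomaly detection in longitudinal difference volumes from breast MRI
screening: an R implementation of a GAN-based analysis chain that asks
whether *negative* screening exams already carry image signatures of lesions
that will only emerge at a later visit.

## Who this is for

Researchers working on dynamic risk profiling in image-based screening:
people who want to model normal inter-visit appearance change, score new
exams against that model, and evaluate whether elevated anomaly scores
predict future lesion emergence — all on data they can actually run, since
the package ships a synthetic longitudinal cohort generator with the same
statistical structure (and accepts real NIfTI volumes with an identical
manifest schema).

## The method

The unit of analysis is the difference volume between consecutive negative
(grade 1) visits, `I_diff(i,j) = I_sub(i) - I_sub(j)`, after registration
and breast segmentation. A model of *normal* change is learned from 2-D
patches of the negative cohort only, as an f-AnoGAN-style trio:

- generator **G** (latent vector → patch) and critic **D**, trained as a
  Wasserstein GAN with gradient penalty;
- encoder **E**, trained afterwards so that `y = G(E(x))` reconstructs
  normal patches (pixel MSE plus critic-feature MSE — the izif objective).

A patch `x` is scored by

```
L(x) = L_R(x) + k · L_D(x),   k = 0.1
L_R  = mean[(x − G(E(x)))²]            (residual score)
L_D  = mean[(f(x) − f(G(E(x))))²]      (critic-feature score)
```

Anomaly maps arise from sliding the scorer across every axial slice and
averaging window scores per voxel; the examination-level score is the
fraction of covered breast-tissue voxels whose map value exceeds a
validation-derived (Youden) patch threshold, a number in [0, 1]. Evaluation
follows the screening design: bootstrap ROC curves (128 patches per cohort,
10 replicates, percentile 95% CIs), lesion-level detection calls (detected
iff ≥ 50% of a lesion's patches are anomalous), and logistic regression of
future lesion presence on the exam score with a scanner-period covariate and
a Wald test at α = 0.05, plus threshold sweeps `T_exam = 0.1 … 0.9` and a
malignancy-stratified regrouping (grades 1–2 vs 3–5).

The adversarial networks are implemented from scratch in base R matrix
algebra (including the closed-form double-backprop of the gradient penalty
for a piecewise-linear critic, verified against finite differences in the
test suite); see the methods vignette in `vignettes/` for the design
rationale, parameter meanings and limitations.

## A worked example

```r
library(anodiff)
report <- runPipeline(demoRunConfig(seed = 1), "demo-run")
```

This generates a 22 + 10 subject synthetic cohort (three visits each, a
planted precursor of contrast 0.5 in the penultimate visit of positives),
registers and differences the visits, trains the GAN and encoder on normal
training patches, and evaluates. With seed 1 it prints/reports:

```
patch_auc_mean               0.956   (bootstrap mean over 10 replicates)
patch_auc_ci_lower           0.942
patch_sensitivity_mean       0.970
patch_specificity_mean       0.852
exam_score_coefficient       15.16
exam_wald_p                  0.0228
mean_exam_score_positive     0.433
mean_exam_score_negative     0.196
lesion_detection_fraction    1.000   (8 of 8 future lesions)
```

Read: patches cut from the future lesion location score far above normal
patches (AUC ≈ 0.96, chance = 0.5); exams that precede a lesion have, on
average, twice the anomalous-voxel fraction of exams that do not; and the
exam score remains a significant predictor (p < 0.05) after adjusting for
the scanner-period confound. Under a null cohort (zero precursor and lesion
contrast) the same pipeline yields an AUC interval straddling 0.5 and a Wald
test that rejects at its nominal 5% rate — see the calibration tests.

All artifacts (cohort NIfTI volumes, manifest, model, score tables, sweeps,
exclusion log, JSON report with content hash) land in the run directory.
`inst/scripts/anodiff-pipeline.R` wraps the same call for shell use.

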