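---
title: "Detecting anomalous longitudinal change in volumetric screening images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting anomalous longitudinal change in volumetric screening images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In high-risk breast MRI screening, subjects return for yearly
contrast-enhanced exams. Most visits are negative (BI-RADS 1), yet a fraction
of subjects later develop a lesion, and in hindsight a substantial share of
those lesions were preceded by subtle appearance changes at the same location
in earlier, still-negative scans. `anodiff` implements an unsupervised
analysis chain that asks two questions: can a model of *normal* inter-visit
tissue change flag such precursor signatures as anomalies, and is an
exam-wide summary of those anomalies associated with future lesion emergence?

The unit of analysis is the inter-visit difference volume

$$I^{\mathrm{diff}}_{i,j} = I^{\mathrm{sub}}_i - I^{\mathrm{sub}}_j,$$

the voxelwise difference of the registered first post-contrast subtracted
volumes of two consecutive negative visits $i > j$. Only pairs of consecutive
grade-1 visits are differenced: the visit at which a lesion is confirmed is
never part of a scored difference image, so every signal the model may find
is by construction *predictive*, not detective.

## The anomaly model

The model of normal change is a generative adversarial network in the
f-AnoGAN family, trained exclusively on 2-D patches cut from difference
volumes of the negative cohort's training split:

1. A Wasserstein GAN with gradient penalty learns the distribution of normal
   patches: the generator $G$ maps a latent vector $z$ to a patch, the critic
   $D$ scores realism, and its penultimate-layer activations define a feature
   map $f(\cdot)$.
2. With $G$ and $D$ frozen, an encoder $E$ learns to invert the generator
   (the izif objective): it minimizes
   $\|x - G(E(x))\|^2_{\mathrm{mean}} + k\,\|f(x) - f(G(E(x)))\|^2_{\mathrm{mean}}$.

A new patch $x$ is scored by reconstructing it as $y = G(E(x))$ and
combining a residual score with a discriminator-feature score:

$$L(x) = L_R(x) + k\,L_D(x), \qquad
  L_R = \mathrm{mean}\big[(x - y)^2\big], \quad
  L_D = \mathrm{mean}\big[(f(x) - f(y))^2\big], \quad k = 0.1 .$$

Patches drawn from normal variability reconstruct well (small $L$); patches
containing change the model has never seen — such as a precursor signature —
reconstruct poorly. Means rather than sums are used in both components so the
score is independent of patch size; the two conventions differ only by a
constant factor and the ROC-based evaluation is invariant to monotone
rescaling.

### Network design

No deep-learning framework is assumed: the networks are dense multi-layer
perceptrons written in base R matrix algebra, with leaky-ReLU hidden units, a
tanh generator output and a linear critic output. The critic has exactly two
hidden layers; for piecewise-linear activations the gradient of the
WGAN-GP penalty $(\|\nabla_x D(\hat x)\| - 1)^2$ with respect to the critic
weights has a closed form (the activation masks are locally constant), which
the package implements directly and verifies against finite differences in
its test suite. Adam with $\beta_1 = 0$, $\beta_2 = 0.9$, five critic steps
per generator step and penalty weight 10 follow standard WGAN-GP practice.

Dense rather than convolutional networks are a deliberate trade-off: at the
patch sizes used here they train in seconds on one CPU, keep the whole method
dependency-free, and preserve every structural element the scoring relies on
(latent generator, critic feature layer, encoder inversion). They would not
be the right choice for full-resolution clinical patches, where a
convolutional backbone is standard.

## From patches to examinations

* **Anomaly maps.** The trained model slides a $p \times p$ window (default
  $p = 64$, stride 16) across every axial slice, evaluating windows whose
  center lies in the breast mask. Each voxel's map value is the mean of $L$
  over all windows covering it — the least-assumptive symmetric fusion rule,
  and one that an exhaustive window-enumeration oracle can verify exactly.
* **Examination-level score.** Voxels are classified anomalous when their map
  value exceeds the deployed patch threshold; the exam score is the fraction
  of covered breast-tissue voxels classified anomalous, which lies in
  $[0, 1]$ by construction. The patch threshold is the mean of the Youden
  thresholds over the validation bootstrap replicates.
* **Lesion-level call.** A future lesion counts as detected when at least
  half of the patches covering its location score above the patch threshold.

## Statistical evaluation

* **Patch level.** Bootstrap ROC analysis: each replicate draws 128 patches
  per cohort (without replacement; smaller pools fall back to sampling with
  replacement and say so), computes an empirical ROC whose trapezoidal AUC
  equals the Mann-Whitney statistic with half credit for ties, and takes the
  Youden-optimal operating point with ties broken toward the more specific
  threshold. Ten replicates yield percentile 95% confidence intervals. The
  128-per-cohort reading of the replicate design (rather than 128 total)
  matches the equal-group-size construction of the replicate ROC curves and
  is configurable.
* **Examination level.** Logistic regression of future lesion presence on
  the exam score with a scanner-period indicator as covariate, Wald test at
  $\alpha = 0.05$ on the score coefficient, a threshold sweep
  $T_{\mathrm{exam}} = 0.1, \ldots, 0.9$ (an exam is called positive iff its
  score strictly exceeds $T_{\mathrm{exam}}$), and a second sweep with the
  positive class redefined as final grade 3-5 (grades 1-2 negative) to weight
  malignancy. Complete or quasi-complete separation is flagged rather than
  reported as a coefficient.

The logistic fit itself is delegated to `stats::glm`; the package's test
suite cross-checks it against an independently written BFGS maximizer of the
log-likelihood, and checks the ROC/Youden machinery against brute-force pair
counting and exhaustive threshold search.

## The synthetic cohort generator

The clinical cohort the method was designed for is not distributable, so the
package ships a generator that reproduces the *statistical structure* the
analysis assumes, without any anatomical claim:

* **Anatomy.** A smooth two-lobed in-plane mask stands in for breast tissue;
  in-mask baseline intensity 1 plus a band-limited Gaussian random field
  (amplitude 0.25, correlation length 4 voxels) stands in for fibroglandular
  texture.
* **Normal inter-visit change.** Each visit re-renders the same anatomy
  through a smooth random in-plane displacement field (default amplitude 1
  voxel), a smooth multiplicative drift field (sd 0.05), and additive
  Gaussian noise (sd 0.05).
* **Scanner confound.** With probability 0.25 a subject's first visit is
  assigned to an earlier acquisition period and receives a global affine
  intensity shift (scale 1.10, offset 0.05). Difference images straddling the
  period switch therefore carry a volume-wide offset — the mechanism that
  produces scanner-linked false positives and motivates the scanner covariate
  in the exam-level regression.
* **Lesions.** Positive subjects receive a Gaussian intensity bump (contrast
  1.0, radius 5 voxels) at the final visit, graded 2-5, and a
  lower-amplitude, wider precursor bump (contrast 0.5) at the same center in
  the penultimate visit. The precursor therefore appears in the last
  difference image of consecutive grade-1 visits — the exam from which
  prediction is evaluated. Nothing is known about real precursor morphology;
  amplitude and extent are free parameters of the simulation, not biological
  claims.
* **Splits.** Negatives are partitioned 75/7/18% into train/validation/test;
  positives 15/85% into validation/test; no subject appears in two splits.

Because lesions and precursors are *planted*, the generator turns the whole
pipeline into a parameter-recovery experiment: with the precursor contrast
well above the noise level the patch score must separate lesion-location
patches from normal patches, and with zero contrast every association must
vanish. What passing these tests does **not** show is performance on real
CE-MRI: real fibroglandular enhancement, contrast kinetics, deformable
anatomy and multi-scanner heterogeneity are all outside the simulation.

## Preprocessing choices

* **Registration.** Follow-ups are registered to the first visit by an
  integer-shift search maximizing masked normalized cross-correlation,
  refined by Nelder-Mead translation and an optional affine stage. The
  post-registration NCC inside the mask is the quality score; subjects below
  the floor (default 0.85) are excluded as misregistered. This is a declared
  desk-scale stand-in — the reference analysis used a dedicated registration
  pipeline whose details are not available — but it recovers known
  translations to sub-voxel accuracy on synthetic series.
* **Segmentation.** Otsu thresholding, largest 6-connected component and
  slicewise morphological closing; in synthetic mode the generator's mask is
  passed through verbatim (the default), keeping segmentation error out of
  the recovery experiments.
* **Patch extraction.** Axial $p \times p$ patches centered on in-mask
  voxels, sampled uniformly without replacement. Any patch whose footprint
  contains more than 50 background pixels is discarded — the rule is applied
  uniformly to normal and lesion-location patches (the reference analysis
  documents it only for lesion patches; uniform application avoids a
  training/evaluation asymmetry). Subjects whose mask admits no eligible
  center are excluded as "breast too small"; positive subjects whose lesion
  patches are all background-excluded leave the patch-level evaluation, with
  the exclusion logged.
* **Coordinates.** Voxel indices are 0-based in (z, y, x) order everywhere a
  coordinate is serialized; a patch centered at $c$ covers
  $[c - \lfloor p/2 \rfloor, \; c - \lfloor p/2 \rfloor + p - 1]$.

## Numerical and design notes

* **Determinism.** Every stage draws its seed from the global run seed via a
  string-tagged integer hash, so per-subject results do not depend on cohort
  ordering, and a rerun under the same configuration reproduces the run
  report bit for bit (the report embeds its own content hash).
* **Exam labels.** The last consecutive grade-1 difference of a positive
  subject is the labeled exam (a lesion is confirmed at the following
  visit); all other exams, including earlier pairs of the same subject,
  carry label 0. By default all consecutive grade-1 pairs of
  validation/test subjects enter the exam-level evaluation, mirroring the
  multiple-exams-per-negative-subject structure of the reference design.
* **Boundary conventions.** Patch-level: a patch with exactly 50 background
  pixels is retained, 51 is excluded. Lesion-level: a detection fraction of
  exactly 0.5 counts as detected. Exam-level: an exam is positive iff its
  score strictly exceeds $T_{\mathrm{exam}}$. Youden ties break toward the
  higher threshold.
* **Problem sizes.** The package's demonstration configuration
  (`demoRunConfig()`) uses 22 negative + 10 positive subjects on a
  $2 \times 40 \times 40$ grid with 16-pixel patches and a compact model
  (latent 16, width 64, 150 generator steps) — chosen so the full chain,
  including bootstrap and regression, runs in about a minute on one CPU
  while every stage remains statistically testable. The type-I-error
  calibration study uses 400 simulated null cohorts of 16 + 16 subjects with
  all-pairs exam evaluation (48 exams per cohort), a size at which the
  asymptotic Wald reference is adequate; registration is switched off there
  since the null volumes share a grid and the study targets the test
  statistic, not the registrar. At these scales the registration quality
  floor is set to 0.8: the attainable NCC shrinks with grid size because the
  random deformation is non-rigid, and the default floor of 0.85 would
  exclude a large fraction of perfectly usable synthetic subjects.
* **Degenerate inputs.** Empty masks, single-class score vectors,
  zero-variance predictors, zero-range normalization statistics and
  separated logistic designs all raise descriptive errors or explicit flags
  rather than propagating silently.

## Limitations

* The adversarial model is deliberately small and dense; absolute score
  scales are meaningless across models, which is why all evaluation is
  rank- or threshold-based and thresholds are always re-derived from
  validation data.
* The registration and segmentation stages are simple stand-ins adequate for
  the synthetic data's rigid-plus-mild-deformation regime, not for clinical
  breast MRI.
* The exam-level aggregation (fraction of classified voxels) is one
  defensible reading of a mean-over-classified-voxels summary bounded in
  $[0, 1]$; other aggregations (e.g., mean raw score) are plausible and
  would require re-deriving exam thresholds.
* Exams of the same subject share visits and are therefore correlated; the
  exam-level regression treats them as independent, as the reference design
  does. The null-calibration study shows the resulting Wald test still holds
  its nominal level under the simulated conditions.

## A worked run

```r
library(anodiff)
config <- demoRunConfig(seed = 1)
report <- runPipeline(config, "demo-run")
report$test$auc_ci        # bootstrap AUC interval on the test patches
report$exam$p_values      # Wald p-values, score + scanner covariate
```

Artifacts land in the run directory: the generated cohort (NIfTI volumes and
a manifest CSV), the trained model, per-patch and per-exam score tables, ROC
replicate metrics, the threshold sweeps, the exclusion log and a JSON report
whose hash reproduces under the same seed.
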