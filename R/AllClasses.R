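#' @import methods
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Configuration of a synthetic longitudinal screening cohort
#'
#' Parameters of the synthetic-cohort generator. The generator emulates the
#' statistical structure the downstream analysis assumes: per-subject series of
#' at least three volumetric subtracted visits with breast masks; a negative
#' cohort whose inter-visit change is normal variability (smooth intensity
#' drift, mild deformation, additive noise, scanner-period intensity shifts);
#' and a positive cohort in which a lesion emerges at the final visit with a
#' lower-amplitude precursor signature at the same location one visit earlier.
#'
#' @slot nNegative,nPositive subject counts per cohort.
#' @slot nVisits visits per subject (at least 3; the first `nVisits - 1` visits
#'   are graded 1).
#' @slot volumeShape voxel grid as (z, y, x).
#' @slot textureCorr,textureAmp correlation length (voxels) and amplitude of
#'   the background tissue texture (a band-limited Gaussian random field).
#' @slot driftSigma standard deviation of the smooth multiplicative inter-visit
#'   intensity drift.
#' @slot deformAmp maximum in-plane displacement (voxels) of the smooth random
#'   inter-visit deformation.
#' @slot noiseSigma additive Gaussian noise standard deviation.
#' @slot lesionContrast peak added intensity of the emerged lesion (final
#'   visit).
#' @slot precursorContrast peak added intensity of the precursor signature in
#'   the penultimate visit; must be strictly below `lesionContrast` unless both
#'   are zero.
#' @slot lesionRadiusVox lesion radius in voxels.
#' @slot scannerShiftProb probability that a subject's first visit was acquired
#'   in the "period 1" protocol, modeled as a global affine intensity shift.
#' @slot seed integer seed; all per-subject randomness is derived from it.
#' @export
setClass("CohortConfig", representation(
  nNegative = "numeric", nPositive = "numeric", nVisits = "numeric",
  volumeShape = "numeric", textureCorr = "numeric", textureAmp = "numeric",
  driftSigma = "numeric", deformAmp = "numeric", noiseSigma = "numeric",
  lesionContrast = "numeric", precursorContrast = "numeric",
  lesionRadiusVox = "numeric", scannerShiftProb = "numeric", seed = "numeric"
))

setValidity("CohortConfig", function(object) {
  v <- cohortConfigViolations(object)
  if (length(v) == 0) TRUE else v
})

#' One subject's ordered series of screening visits
#'
#' @slot subjectId subject identifier.
#' @slot visits list of visits in acquisition order; each visit is a list with
#'   elements `volume` (3-D array, the first post-contrast subtracted volume),
#'   `mask` (3-D binary array of breast tissue), `grade` (ordinal 1-5,
#'   BI-RADS-like), `scannerPeriod` (1, 2 or 3).
#' @slot lesionMask 3-D binary array of the future lesion footprint (positive
#'   cohort only, otherwise `NULL`).
#' @slot cohort `"negative"` or `"positive"`.
#' @export
setClass("SubjectSeries", representation(
  subjectId = "character", visits = "list",
  lesionMask = "arrayOrNULL", cohort = "character"
))

setValidity("SubjectSeries", function(object) {
  msgs <- character(0)
  if (!object@cohort %in% c("negative", "positive"))
    msgs <- c(msgs, "cohort must be 'negative' or 'positive'")
  n <- length(object@visits)
  if (n > 0) {
    grades <- vapply(object@visits, `[[`, numeric(1), "grade")
    if (n > 1 && any(grades[seq_len(n - 1)] != 1))
      msgs <- c(msgs, "grades of all visits before the last must equal 1")
    if (object@cohort == "positive" && grades[n] <= 1)
      msgs <- c(msgs, "positive subject must have final grade > 1")
    if (object@cohort == "negative" && grades[n] != 1)
      msgs <- c(msgs, "negative subject must have final grade 1")
  }
  if (object@cohort == "positive" && is.null(object@lesionMask))
    msgs <- c(msgs, "positive subject requires a lesion mask")
  if (object@cohort == "negative" && !is.null(object@lesionMask))
    msgs <- c(msgs, "negative subject must not carry a lesion mask")
  if (!is.null(object@lesionMask) && n > 0) {
    m <- object@visits[[1]]$mask
    if (any(object@lesionMask == 1 & m == 0))
      msgs <- c(msgs, "lesion mask must lie inside the breast mask")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Voxelwise difference of two registered visits
#'
#' Holds the signed difference volume between subtracted volumes of
#' two visits (later minus earlier), together with the intersection of the two
#' visits' breast masks and the scanner periods involved.
#'
#' @slot values signed 3-D array.
#' @slot mask 3-D binary array (logical AND of the two visits' masks).
#' @slot visitPair integer pair (i, j) with i > j.
#' @slot scannerPair scanner periods of visits i and j.
#' @slot subjectId subject identifier.
#' @export
setClass("DifferenceVolume", representation(
  values = "array", mask = "array", visitPair = "numeric",
  scannerPair = "numeric", subjectId = "character"
))

setValidity("DifferenceVolume", function(object) {
  msgs <- character(0)
  if (!identical(dim(object@values), dim(object@mask)))
    msgs <- c(msgs, "values and mask must share a shape")
  if (length(object@visitPair) == 2 && object@visitPair[1] <= object@visitPair[2])
    msgs <- c(msgs, "visitPair must satisfy i > j")
  if (length(msgs) == 0) TRUE else msgs
})

#' A set of 2-D patches cut from a difference volume
#'
#' @slot pixels array of shape (p, p, n): n patches of side p. May hold zero
#'   patches when extraction found no eligible center (see `reason`).
#' @slot centers n x 3 matrix of 0-based voxel coordinates (z, y, x) of patch
#'   centers in the source difference volume.
#' @slot label per-patch label, `"normal"` or `"future_lesion"`.
#' @slot nBackground per-patch count of pixels outside the breast mask.
#' @slot subjectId,visitPair provenance of the source difference volume.
#' @slot reason zero-length when extraction succeeded; otherwise a single
#'   exclusion reason such as `"excluded: breast too small"`.
#' @export
setClass("PatchSet", representation(
  pixels = "array", centers = "matrix", label = "character",
  nBackground = "numeric", subjectId = "character", visitPair = "numeric",
  reason = "character"
))

setValidity("PatchSet", function(object) {
  msgs <- character(0)
  n <- dim(object@pixels)[3]
  if (nrow(object@centers) != n || length(object@label) != n ||
      length(object@nBackground) != n)
    msgs <- c(msgs, "pixels, centers, label and nBackground disagree on patch count")
  if (dim(object@pixels)[1] != dim(object@pixels)[2])
    msgs <- c(msgs, "patches must be square")
  if (length(msgs) == 0) TRUE else msgs
})

#' Trained generative anomaly model
#'
#' Bundles the generator G, critic D and encoder E of the adversarial anomaly
#' detector together with everything needed to score new patches: the score
#' weighting `k`, the patch side the networks expect, and the training-split
#' intensity statistics used to normalize inputs.
#'
#' @slot G,D,E network parameter lists (see [trainWGAN()], [trainEncoder()]).
#' @slot latentDim dimension of the noise space z.
#' @slot k weighting of the discriminator score in L = L_R + k * L_D
#'   (default 0.1).
#' @slot patchSide patch side p the networks consume.
#' @slot normStats list with `lower`/`upper` intensity bounds mapping raw patch
#'   values to the model range \[-1, 1\].
#' @slot trainingConfig record of architecture, optimizer settings, step counts
#'   and seeds.
#' @slot trainingLog data.frame of loss trajectories.
#' @export
setClass("AnomalyModel", representation(
  G = "list", D = "list", E = "list", latentDim = "numeric", k = "numeric",
  patchSide = "numeric", normStats = "list", trainingConfig = "list",
  trainingLog = "data.frame"
))

setValidity("AnomalyModel", function(object) {
  msgs <- character(0)
  if (object@k < 0) msgs <- c(msgs, "k must be non-negative")
  if (length(msgs) == 0) TRUE else msgs
})

#' Voxelwise anomaly-score map for one examination
#'
#' @slot values 3-D array of voxel anomaly scores: the mean of the local score
#'   L over all sliding windows covering the voxel; `NA` outside the mask or
#'   where no window contributed.
#' @slot coverage 3-D integer array counting contributing windows per voxel.
#' @slot mask breast mask of the source difference volume.
#' @slot subjectId,visitPair provenance.
#' @export
setClass("AnomalyMap", representation(
  values = "array", coverage = "array", mask = "array",
  subjectId = "character", visitPair = "numeric"
))

#' Examination-level anomaly score
#'
#' The fraction of covered breast-tissue voxels classified anomalous at the
#' deployed patch threshold; lies in \[0, 1\] by construction.
#'
#' @slot score scalar in \[0, 1\].
#' @slot patchThreshold threshold used to classify voxels.
#' @slot nVoxels number of covered mask voxels aggregated.
#' @slot subjectId,visitPair provenance.
#' @slot scannerPair scanner periods of the two visits.
#' @export
setClass("ExamScore", representation(
  score = "numeric", patchThreshold = "numeric", nVoxels = "numeric",
  subjectId = "character", visitPair = "numeric", scannerPair = "numeric"
))

setValidity("ExamScore", function(object) {
  msgs <- character(0)
  if (object@score < 0 || object@score > 1) msgs <- c(msgs, "score must lie in [0, 1]")
  if (object@nVoxels <= 0) msgs <- c(msgs, "nVoxels must be positive")
  if (length(msgs) == 0) TRUE else msgs
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nNegative, "negative +", object@nPositive,
      "positive subjects,", object@nVisits, "visits each\n")
  cat("  volume", paste(object@volumeShape, collapse = "x"),
      "| texture corr", object@textureCorr, "amp", object@textureAmp, "\n")
  cat("  drift", object@driftSigma, "| deform", object@deformAmp,
      "| noise", object@noiseSigma, "\n")
  cat("  lesion contrast", object@lesionContrast, "(precursor",
      object@precursorContrast, ", radius", object@lesionRadiusVox, "vox)\n")
  cat("  P(period-1 first visit)", object@scannerShiftProb,
      "| seed", object@seed, "\n")
})

setMethod("show", "SubjectSeries", function(object) {
  grades <- vapply(object@visits, `[[`, numeric(1), "grade")
  cat("SubjectSeries", object@subjectId, sprintf("(%s cohort)", object@cohort),
      "-", length(object@visits), "visits, grades:",
      paste(grades, collapse = " "), "\n")
})

setMethod("show", "DifferenceVolume", function(object) {
  cat("DifferenceVolume", object@subjectId,
      sprintf("visits %d-%d,", object@visitPair[1], object@visitPair[2]),
      paste(dim(object@values), collapse = "x"), "voxels,",
      sum(object@mask), "in mask\n")
})

setMethod("show", "PatchSet", function(object) {
  cat("PatchSet:", dim(object@pixels)[3], "patches of side",
      dim(object@pixels)[1], "from", object@subjectId, "\n")
  if (length(object@reason) > 0) cat("  flagged:", object@reason, "\n")
})

setMethod("show", "AnomalyModel", function(object) {
  cat("AnomalyModel: patches", object@patchSide, "x", object@patchSide,
      "| latent dim", object@latentDim, "| k =", object@k, "\n")
})

setMethod("show", "AnomalyMap", function(object) {
  cat("AnomalyMap", object@subjectId,
      sprintf("visits %d-%d:", object@visitPair[1], object@visitPair[2]),
      sum(!is.na(object@values)), "scored voxels\n")
})

setMethod("show", "ExamScore", function(object) {
  cat(sprintf("ExamScore %.4f (%s visits %d-%d, %d voxels, threshold %.4g)\n",
              object@score, object@subjectId, object@visitPair[1],
              object@visitPair[2], as.integer(object@nVoxels),
              object@patchThreshold))
})

#' @describeIn ExamScore-class numeric score value
#' @param x an `ExamScore` (or other object with a score).
#' @export
examScore <- function(x) x@score

#' Accessors for difference volumes and patch sets
#'
#' `diffValues`/`diffMask` return the signed values and breast mask of a
#' [DifferenceVolume-class]; `patchMatrix` flattens a [PatchSet-class] into an
#' n x p^2 matrix (one row per patch, column-major pixel order) ready for the
#' model; `patchLabels` and `patchCenters` return patch metadata.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
diffValues <- function(x) x@values

#' @rdname accessors
#' @export
diffMask <- function(x) x@mask

#' @rdname accessors
#' @export
patchMatrix <- function(x) {
  p <- dim(x@pixels)[1]
  n <- dim(x@pixels)[3]
  if (n == 0) return(matrix(numeric(0), nrow = 0, ncol = p * p))
  t(matrix(x@pixels, nrow = p * p, ncol = n))
}

#' @rdname accessors
#' @export
patchLabels <- function(x) x@label

#' @rdname accessors
#' @export
patchCenters <- function(x) x@centers
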