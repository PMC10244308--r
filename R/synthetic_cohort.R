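#' Construct a synthetic-cohort configuration
#'
#' Defaults mirror the screening-study design the package emulates: a negative
#' cohort (44 subjects) whose visits stay grade 1 throughout, a positive cohort
#' (20 subjects) whose final visit carries an emerged lesion graded above 1,
#' at least three visits per subject, and a period-1 scanner-protocol intensity
#' shift affecting a fraction of first visits.
#'
#' @param nNegative,nPositive subject counts.
#' @param nVisits visits per subject, at least 3.
#' @param volumeShape voxel grid (z, y, x).
#' @param textureCorr,textureAmp tissue-texture correlation length (voxels) and
#'   amplitude (intensity units; the in-mask baseline intensity is 1).
#' @param driftSigma std of the smooth multiplicative inter-visit drift field.
#' @param deformAmp max in-plane displacement (voxels) of the smooth random
#'   inter-visit deformation.
#' @param noiseSigma additive Gaussian noise std.
#' @param lesionContrast peak added intensity of the lesion at the final visit.
#' @param precursorContrast peak added intensity of the precursor signature at
#'   the same location in the penultimate visit; strictly less than
#'   `lesionContrast` unless both are zero.
#' @param lesionRadiusVox lesion radius in voxels.
#' @param scannerShiftProb probability a subject's first visit uses the shifted
#'   period-1 intensity scale.
#' @param seed integer master seed.
#' @return a validated [CohortConfig-class].
#' @export
cohortConfig <- function(nNegative = 44, nPositive = 20, nVisits = 3,
                         volumeShape = c(4, 96, 96),
                         textureCorr = 4, textureAmp = 0.25,
                         driftSigma = 0.05, deformAmp = 1.0,
                         noiseSigma = 0.05,
                         lesionContrast = 1.0, precursorContrast = 0.5,
                         lesionRadiusVox = 5, scannerShiftProb = 0.25,
                         seed = 1L) {
  new("CohortConfig", nNegative = nNegative, nPositive = nPositive,
      nVisits = nVisits, volumeShape = volumeShape, textureCorr = textureCorr,
      textureAmp = textureAmp, driftSigma = driftSigma, deformAmp = deformAmp,
      noiseSigma = noiseSigma, lesionContrast = lesionContrast,
      precursorContrast = precursorContrast, lesionRadiusVox = lesionRadiusVox,
      scannerShiftProb = scannerShiftProb, seed = seed)
}

cohortConfigViolations <- function(config) {
  msgs <- character(0)
  if (config@nVisits < 3)
    msgs <- c(msgs, "nVisits: at least three visits per subject are required")
  if (length(config@volumeShape) != 3 || any(config@volumeShape < 1))
    msgs <- c(msgs, "volumeShape: must be three positive extents (z, y, x)")
  for (f in c("textureAmp", "driftSigma", "deformAmp", "noiseSigma",
              "lesionContrast", "precursorContrast", "scannerShiftProb"))
    if (slot(config, f) < 0) msgs <- c(msgs, paste0(f, ": must be non-negative"))
  if (config@precursorContrast > 0 &&
      config@precursorContrast >= config@lesionContrast)
    msgs <- c(msgs, "precursorContrast: must be strictly below lesionContrast")
  if (config@scannerShiftProb > 1)
    msgs <- c(msgs, "scannerShiftProb: must be a probability")
  if (config@nNegative < 1 || config@nPositive < 0)
    msgs <- c(msgs, "nNegative/nPositive: need at least one negative subject")
  if (length(config@volumeShape) == 3) {
    need <- 2 * (config@lesionRadiusVox + 3)
    for (d in 2:3) {
      if (config@volumeShape[d] < need)
        msgs <- c(msgs, sprintf(
          "volumeShape[%d] = %d too small to contain the lesion (need >= %d): %s axis",
          d, config@volumeShape[d], need, c("", "y", "x")[d]))
    }
  }
  msgs
}

## In-plane breast-tissue mask: a smooth two-lobed superellipse (both breasts
## handled implicitly as one tissue region), replicated across slices.
breastMask <- function(shape) {
  z <- shape[1]; ny <- shape[2]; nx <- shape[3]
  yc <- (ny + 1) / 2; xc <- (nx + 1) / 2
  ry <- ny * 0.44; rx <- nx * 0.46
  g <- expand.grid(y = seq_len(ny), x = seq_len(nx))
  # superellipse with a mild medial waist along x
  waist <- 1 - 0.10 * exp(-((g$x - xc) / (nx * 0.08))^2)
  r <- (abs(g$y - yc) / (ry * waist))^3 + (abs(g$x - xc) / rx)^3
  sl <- matrix(as.integer(r <= 1), nrow = ny, ncol = nx)
  array(rep(sl, each = z), dim = c(z, ny, nx))
}

gaussianBlob <- function(shape, center, sigmaPlane, sigmaZ = 1) {
  g <- expand.grid(z = seq_len(shape[1]), y = seq_len(shape[2]), x = seq_len(shape[3]))
  v <- exp(-((g$y - center[2])^2 + (g$x - center[3])^2) / (2 * sigmaPlane^2)) *
    exp(-(g$z - center[1])^2 / (2 * sigmaZ^2))
  array(v, dim = shape)
}

## Constants of the period-1 scanner intensity shift (global affine rescale of
## the first visit when that visit falls into period 1).
PERIOD1_SCALE <- 1.10
PERIOD1_OFFSET <- 0.05

#' Generate one synthetic subject series
#'
#' Deterministic given `(config, subjectSeed)`. Each visit is the shared base
#' anatomy (breast mask times 1 + texture) carried through a smooth random
#' in-plane deformation, multiplied by a smooth drift field, plus additive
#' noise. Positive subjects additionally receive a Gaussian lesion bump at the
#' final visit and a lower-amplitude, wider precursor bump at the same center
#' in the penultimate visit, so the precursor appears in the last difference
#' image of consecutive grade-1 visits.
#'
#' @param config a [CohortConfig-class].
#' @param cohort `"negative"` or `"positive"`.
#' @param subjectSeed integer seed for this subject (derive from the config
#'   seed via [deriveSeed()] for cohort-level reproducibility).
#' @param subjectId identifier stored in the series.
#' @return a [SubjectSeries-class].
#' @export
generateSubject <- function(config, cohort = c("negative", "positive"),
                            subjectSeed, subjectId = NULL) {
  cohort <- match.arg(cohort)
  viol <- cohortConfigViolations(config)
  if (length(viol) > 0) stop("invalid CohortConfig: ", paste(viol, collapse = "; "))
  shape <- config@volumeShape
  if (is.null(subjectId)) subjectId <- sprintf("S%09d", subjectSeed %% 1e9)

  set.seed(subjectSeed)
  mask <- breastMask(shape)
  base <- (1 + config@textureAmp * smoothNoiseField(shape, config@textureCorr)) * mask

  nV <- config@nVisits
  period1 <- stats::runif(1) < config@scannerShiftProb

  lesionCenter <- NULL
  lesionMask <- NULL
  if (cohort == "positive") {
    margin <- config@lesionRadiusVox + 2
    ok <- array(FALSE, dim = shape)
    ys <- seq_len(shape[2]); xs <- seq_len(shape[3])
    inner <- mask
    # candidate centers: mask voxels whose full in-plane lesion disc is in-mask
    for (dz in 0) {
      cand <- which(mask == 1, arr.ind = TRUE)
      keep <- rep(TRUE, nrow(cand))
      offs <- expand.grid(dy = c(-margin, 0, margin), dx = c(-margin, 0, margin))
      for (k in seq_len(nrow(offs))) {
        yy <- cand[, 2] + offs$dy[k]; xx <- cand[, 3] + offs$dx[k]
        inb <- yy >= 1 & yy <= shape[2] & xx >= 1 & xx <= shape[3]
        inm <- inb
        inm[inb] <- mask[cbind(cand[inb, 1], yy[inb], xx[inb])] == 1
        keep <- keep & inm
      }
      ok[cand[keep, , drop = FALSE]] <- TRUE
    }
    candIdx <- which(ok)
    if (length(candIdx) == 0)
      stop(sprintf(
        "volume too small to place a lesion of radius %d inside the breast mask (in-plane extent %dx%d)",
        config@lesionRadiusVox, shape[2], shape[3]))
    pick <- candIdx[sample.int(length(candIdx), 1)]
    lesionCenter <- as.numeric(arrayInd(pick, shape))
    g <- expand.grid(z = seq_len(shape[1]), y = seq_len(shape[2]), x = seq_len(shape[3]))
    rz <- max(min(config@lesionRadiusVox, 1), 1)
    d2 <- ((g$z - lesionCenter[1]) / rz)^2 +
      ((g$y - lesionCenter[2]) / config@lesionRadiusVox)^2 +
      ((g$x - lesionCenter[3]) / config@lesionRadiusVox)^2
    lesionMask <- array(as.integer(d2 <= 1), dim = shape) * mask
    storage.mode(lesionMask) <- "integer"
  }

  visits <- vector("list", nV)
  for (v in seq_len(nV)) {
    if (config@deformAmp > 0) {
      dy <- config@deformAmp * smoothNoiseField(shape, max(config@textureCorr * 2, 4))
      dx <- config@deformAmp * smoothNoiseField(shape, max(config@textureCorr * 2, 4))
      dy <- dy / max(abs(dy), 1e-9) * config@deformAmp
      dx <- dx / max(abs(dx), 1e-9) * config@deformAmp
      g <- expand.grid(z = seq_len(shape[1]), y = seq_len(shape[2]), x = seq_len(shape[3]))
      vol <- array(trilinearSample(base, g$z, g$y + as.vector(dy), g$x + as.vector(dx)),
                   dim = shape)
    } else vol <- base
    if (config@driftSigma > 0) {
      drift <- 1 + config@driftSigma * smoothNoiseField(shape, max(shape[2] / 6, 4))
      vol <- vol * drift
    }
    if (cohort == "positive") {
      sigmaL <- config@lesionRadiusVox / 2
      if (v == nV && config@lesionContrast > 0)
        vol <- vol + config@lesionContrast *
          gaussianBlob(shape, lesionCenter, sigmaL)
      if (v == nV - 1 && config@precursorContrast > 0)
        vol <- vol + config@precursorContrast *
          gaussianBlob(shape, lesionCenter, sigmaL * 1.5)
    }
    periodV <- if (v == 1 && period1) 1L else 2L
    if (periodV == 1L)
      vol <- (PERIOD1_SCALE * vol + PERIOD1_OFFSET) * mask
    if (config@noiseSigma > 0)
      vol <- vol + config@noiseSigma * array(stats::rnorm(prod(shape)), dim = shape)
    grade <- 1
    if (cohort == "positive" && v == nV)
      grade <- sample(2:5, 1, prob = c(0.35, 0.30, 0.20, 0.15))
    visits[[v]] <- list(volume = vol, mask = mask, grade = grade,
                        scannerPeriod = periodV)
  }

  new("SubjectSeries", subjectId = subjectId, visits = visits,
      lesionMask = lesionMask, cohort = cohort)
}

## Split counts by largest-remainder apportionment, guaranteeing at least one
## subject in every split that has positive target share (when n allows).
apportionSplits <- function(n, shares) {
  raw <- n * shares
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  # ensure nonempty splits where share > 0, stealing from the largest split
  for (i in seq_along(shares)) {
    if (shares[i] > 0 && counts[i] == 0 && n >= sum(shares > 0)) {
      donor <- which.max(counts)
      counts[donor] <- counts[donor] - 1
      counts[i] <- counts[i] + 1
    }
  }
  counts
}

#' Generate and serialize a full synthetic cohort
#'
#' Writes every subject's visit volumes and masks as NIfTI-1 (`.nii.gz`), the
#' positive subjects' lesion masks as uint8 NIfTI, a manifest CSV (one row per
#' visit) and a YAML copy of the configuration. Subjects are assigned to
#' train/validation/test splits at the study proportions: negatives 75/7/18,
#' positives 0/15/85 (no subject appears in two splits).
#'
#' @param config a [CohortConfig-class].
#' @param outDir output directory.
#' @param overwrite refuse to write into an existing non-empty directory unless
#'   `TRUE`.
#' @return the manifest `data.frame`, invisibly.
#' @export
generateCohort <- function(config, outDir, overwrite = FALSE) {
  viol <- cohortConfigViolations(config)
  if (length(viol) > 0) stop("invalid CohortConfig: ", paste(viol, collapse = "; "))
  if (dir.exists(outDir) && length(list.files(outDir)) > 0 && !overwrite)
    stop("output directory exists and is non-empty; pass overwrite = TRUE")
  dir.create(file.path(outDir, "volumes"), recursive = TRUE, showWarnings = FALSE)

  ids <- c(sprintf("neg%03d", seq_len(config@nNegative)),
           sprintf("pos%03d", seq_len(config@nPositive)))
  cohorts <- c(rep("negative", config@nNegative), rep("positive", config@nPositive))

  set.seed(deriveSeed(config@seed, "splits"))
  negSplit <- rep(c("train", "validation", "test"),
                  apportionSplits(config@nNegative, c(0.75, 0.07, 0.18)))
  negSplit <- sample(negSplit)
  posSplit <- rep(c("validation", "test"),
                  apportionSplits(config@nPositive, c(0.15, 0.85)))
  posSplit <- if (config@nPositive > 0) sample(posSplit) else character(0)
  splits <- c(negSplit, posSplit)

  rows <- list()
  for (s in seq_along(ids)) {
    series <- generateSubject(config, cohorts[s],
                              subjectSeed = deriveSeed(config@seed, "subject", ids[s]),
                              subjectId = ids[s])
    lesionPath <- NA_character_
    if (!is.null(series@lesionMask)) {
      lesionPath <- file.path("volumes", paste0(ids[s], "_lesion.nii.gz"))
      m <- series@lesionMask; storage.mode(m) <- "integer"
      RNifti::writeNifti(m, file.path(outDir, lesionPath), datatype = "uint8")
    }
    for (v in seq_along(series@visits)) {
      vis <- series@visits[[v]]
      volPath <- file.path("volumes", sprintf("%s_v%02d.nii.gz", ids[s], v))
      maskPath <- file.path("volumes", sprintf("%s_v%02d_mask.nii.gz", ids[s], v))
      RNifti::writeNifti(vis$volume, file.path(outDir, volPath), datatype = "double")
      mm <- vis$mask; storage.mode(mm) <- "integer"
      RNifti::writeNifti(mm, file.path(outDir, maskPath), datatype = "uint8")
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = ids[s], cohort = cohorts[s], visit_index = v,
        grade = vis$grade, scanner_period = vis$scannerPeriod,
        volume_path = volPath, mask_path = maskPath,
        lesion_mask_path = lesionPath, split = splits[s],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(cohortConfigAsList(config), file.path(outDir, "cohort_config.yaml"))
  invisible(manifest)
}

cohortConfigAsList <- function(config) {
  out <- lapply(slotNames(config), function(s) slot(config, s))
  names(out) <- slotNames(config)
  out
}

#' Load one subject's series from a serialized cohort
#'
#' @param manifest manifest `data.frame` as written by [generateCohort()] (or a
#'   real-data manifest with the same schema).
#' @param subjectId which subject to load.
#' @param dir cohort root directory the manifest paths are relative to.
#' @return a [SubjectSeries-class].
#' @export
loadSubjectSeries <- function(manifest, subjectId, dir) {
  rows <- manifest[manifest$subject_id == subjectId, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown subject: ", subjectId)
  rows <- rows[order(rows$visit_index), , drop = FALSE]
  visits <- lapply(seq_len(nrow(rows)), function(i) {
    vol <- asPlainArray(RNifti::readNifti(file.path(dir, rows$volume_path[i])))
    msk <- asPlainArray(RNifti::readNifti(file.path(dir, rows$mask_path[i])))
    list(volume = vol, mask = msk, grade = rows$grade[i],
         scannerPeriod = rows$scanner_period[i])
  })
  lesion <- NULL
  if (!is.na(rows$lesion_mask_path[1]) && nzchar(rows$lesion_mask_path[1]))
    lesion <- asPlainArray(RNifti::readNifti(file.path(dir, rows$lesion_mask_path[1])))
  new("SubjectSeries", subjectId = subjectId, visits = visits,
      lesionMask = lesion, cohort = rows$cohort[1])
}

asPlainArray <- function(x) array(as.numeric(x), dim = dim(x))
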