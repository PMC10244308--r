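#' Register a follow-up visit to a fixed visit
#'
#' Intensity-based registration used to bring follow-up visits into spatial
#' correspondence with the first visit before differencing: an exhaustive
#' integer-shift search maximizing masked normalized cross-correlation (NCC),
#' refined by a continuous rigid (translation) Nelder-Mead step and optionally
#' a full affine refinement. The attained NCC inside the fixed mask is attached
#' as a quality score; registrations below `qualityFloor` are flagged
#' `"excluded: misregistration"`.
#'
#' @param moving,fixed 3-D volumes on the same voxel grid.
#' @param movingMask,fixedMask binary masks for the two volumes.
#' @param maxShift integer search radius (voxels) for the initial translation,
#'   as (z, y, x).
#' @param affine if `TRUE` (default) refine with a 12-parameter affine after
#'   the rigid stage.
#' @param qualityFloor minimum acceptable NCC (default 0.85).
#' @return a list of class `"registrationResult"` with elements `volume` and
#'   `mask` (resampled moving volume and mask), `transform` (4 x 4 voxel-space
#'   affine, target to source), `quality`, `excluded`, `reason`.
#' @export
registerFollowup <- function(moving, fixed, movingMask, fixedMask,
                             maxShift = c(1, 4, 4), affine = TRUE,
                             qualityFloor = 0.85) {
  if (!identical(dim(moving), dim(fixed)))
    stop(sprintf("shape mismatch: moving %s vs fixed %s",
                 paste(dim(moving), collapse = "x"),
                 paste(dim(fixed), collapse = "x")))
  d <- dim(fixed)
  sel <- which(fixedMask == 1)
  ncc <- function(resampled) {
    a <- fixed[sel]; b <- resampled[sel]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-1)
    stats::cor(a, b)
  }
  translationMatrix <- function(t) {
    A <- diag(4); A[1:3, 4] <- t; A
  }
  scoreShift <- function(t) ncc(resampleAffine(moving, translationMatrix(t)))

  # stage 1: integer shift search
  grid <- expand.grid(z = -maxShift[1]:maxShift[1],
                      y = -maxShift[2]:maxShift[2],
                      x = -maxShift[3]:maxShift[3])
  best <- c(0, 0, 0); bestQ <- -Inf
  for (i in seq_len(nrow(grid))) {
    t <- as.numeric(grid[i, ])
    q <- scoreShift(t)
    if (q > bestQ + 1e-12) { bestQ <- q; best <- t }
  }
  # stage 2: continuous rigid refinement
  opt <- stats::optim(best, function(t) -scoreShift(t), method = "Nelder-Mead",
                      control = list(maxit = 60, reltol = 1e-6))
  if (-opt$value > bestQ) { best <- opt$par; bestQ <- -opt$value }
  A <- translationMatrix(best)
  # stage 3: affine refinement (linear part + translation)
  if (affine) {
    par0 <- c(as.vector(diag(3)), best)
    center <- (d + 1) / 2
    buildA <- function(par) {
      M <- matrix(par[1:9], 3, 3)
      t <- par[10:12]
      A <- diag(4)
      A[1:3, 1:3] <- M
      A[1:3, 4] <- t + center - M %*% center
      A
    }
    optA <- stats::optim(par0, function(par) -ncc(resampleAffine(moving, buildA(par))),
                         method = "Nelder-Mead",
                         control = list(maxit = 150, reltol = 1e-6))
    if (-optA$value > bestQ + 1e-9) { A <- buildA(optA$par); bestQ <- -optA$value }
  }
  outVol <- resampleAffine(moving, A)
  outMask <- resampleAffine(movingMask, A)
  outMask <- array(as.integer(outMask >= 0.5), dim = d)
  q <- ncc(outVol)
  structure(list(volume = outVol, mask = outMask, transform = A, quality = q,
                 excluded = q < qualityFloor,
                 reason = if (q < qualityFloor) "excluded: misregistration" else NA_character_),
            class = "registrationResult")
}

#' Segment breast tissue in a volume
#'
#' Otsu threshold on the volume histogram, followed by the largest 6-connected
#' component and a slicewise morphological closing. In synthetic mode the
#' generator's ground-truth mask may be passed through verbatim.
#'
#' @param volume 3-D scalar volume.
#' @param passthroughMask if not `NULL`, returned unchanged (synthetic mode).
#' @param closingSize odd diameter of the disc structuring element.
#' @return a list of class `"segmentationResult"` with elements `mask`,
#'   `excluded`, `reason`; an empty mask is flagged
#'   `"excluded: segmentation"`.
#' @export
segmentBreast <- function(volume, passthroughMask = NULL, closingSize = 5) {
  if (!is.null(passthroughMask)) {
    m <- passthroughMask
    storage.mode(m) <- "integer"
    return(structure(list(mask = m, excluded = FALSE, reason = NA_character_),
                     class = "segmentationResult"))
  }
  rng <- range(volume)
  if (diff(rng) == 0) {
    return(structure(list(mask = array(0L, dim = dim(volume)), excluded = TRUE,
                          reason = "excluded: segmentation"),
                     class = "segmentationResult"))
  }
  scaled <- (volume - rng[1]) / diff(rng)
  thr <- EBImage::otsu(matrix(scaled, nrow = dim(volume)[1]), range = c(0, 1))
  mask <- array(as.integer(scaled > thr), dim = dim(volume))
  if (sum(mask) == 0)
    return(structure(list(mask = mask, excluded = TRUE,
                          reason = "excluded: segmentation"),
                     class = "segmentationResult"))
  mask <- largestComponent3D(mask)
  # closing on axial slices (frames along the 3rd EBImage dimension)
  kern <- EBImage::makeBrush(closingSize, shape = "disc")
  slices <- aperm(mask, c(2, 3, 1))
  closed <- EBImage::closing(slices, kern)
  mask <- aperm(array(as.integer(closed > 0), dim = dim(slices)), c(3, 1, 2))
  excluded <- sum(mask) == 0
  structure(list(mask = mask, excluded = excluded,
                 reason = if (excluded) "excluded: segmentation" else NA_character_),
            class = "segmentationResult")
}

#' Voxelwise difference of two registered visits
#'
#' Computes the signed inter-visit difference (visit i minus
#' visit j, i > j) on a common grid; the carried mask is the logical AND of the
#' two visits' breast masks.
#'
#' @param volumeI,volumeJ subtracted volumes of visits i and j.
#' @param maskI,maskJ breast masks of the two visits.
#' @param visitPair integer pair `c(i, j)` with i > j.
#' @param scannerPair scanner periods of visits i and j.
#' @param subjectId provenance string.
#' @return a [DifferenceVolume-class].
#' @export
computeDifference <- function(volumeI, volumeJ, maskI, maskJ,
                              visitPair = c(2L, 1L), scannerPair = c(2L, 2L),
                              subjectId = "subject") {
  if (!identical(dim(volumeI), dim(volumeJ)))
    stop(sprintf("shape mismatch: visit i %s vs visit j %s",
                 paste(dim(volumeI), collapse = "x"),
                 paste(dim(volumeJ), collapse = "x")))
  mask <- array(as.integer(maskI == 1 & maskJ == 1), dim = dim(volumeI))
  new("DifferenceVolume", values = volumeI - volumeJ, mask = mask,
      visitPair = as.numeric(visitPair), scannerPair = as.numeric(scannerPair),
      subjectId = subjectId)
}

#' All difference volumes of consecutive grade-1 visits in a series
#'
#' Only pairs of consecutive visits that are both graded 1 are differenced;
#' visits carrying a lesion (grade above 1) are never part of a scored
#' difference image.
#'
#' @param series a [SubjectSeries-class] (registered to a common grid).
#' @return list of [DifferenceVolume-class], ordered by visit pair.
#' @export
subjectDifferences <- function(series) {
  grades <- vapply(series@visits, `[[`, numeric(1), "grade")
  out <- list()
  for (i in seq_len(length(series@visits) - 1)) {
    if (grades[i] == 1 && grades[i + 1] == 1) {
      vi <- series@visits[[i + 1]]; vj <- series@visits[[i]]
      out[[length(out) + 1]] <- computeDifference(
        vi$volume, vj$volume, vi$mask, vj$mask,
        visitPair = c(i + 1L, i), scannerPair = c(vi$scannerPeriod, vj$scannerPeriod),
        subjectId = series@subjectId)
    }
  }
  out
}

## Eligible patch centers in one axial slice: center voxel inside the mask,
## full p x p footprint inside the slice, and at most `backgroundLimit` pixels
## outside the mask within the footprint. Returns a matrix of (y, x, nbg)
## rows (1-based centers).
eligibleCentersSlice <- function(maskSlice, p, backgroundLimit) {
  d <- dim(maskSlice)
  off <- floor(p / 2)
  counts <- backgroundCounts(maskSlice, p)
  res <- NULL
  tl <- which(!is.na(counts) & counts <= backgroundLimit, arr.ind = TRUE)
  if (nrow(tl) == 0) return(matrix(numeric(0), ncol = 3))
  cy <- tl[, 1] + off; cx <- tl[, 2] + off
  inMask <- maskSlice[cbind(cy, cx)] == 1
  cbind(cy, cx, counts[tl])[inMask, , drop = FALSE]
}

cutPatch <- function(values, z, cy, cx, p) {
  off <- floor(p / 2)
  values[z, (cy - off):(cy - off + p - 1), (cx - off):(cx - off + p - 1)]
}

newPatchSet <- function(p, pixels, centers, label, nBackground, diff, reason = character(0)) {
  n <- length(label)
  new("PatchSet",
      pixels = array(pixels, dim = c(p, p, n)),
      centers = matrix(centers, ncol = 3,
                       dimnames = list(NULL, c("z", "y", "x"))),
      label = label, nBackground = as.numeric(nBackground),
      subjectId = diff@subjectId, visitPair = diff@visitPair, reason = reason)
}

#' Extract random normal patches from a difference volume
#'
#' Axial 2-D patches of side `p` whose center lies in the breast mask, sampled
#' uniformly without replacement over eligible centers. Candidate patches with
#' more than `backgroundLimit` pixels outside the mask are never emitted. When
#' fewer than `n` eligible centers exist all of them are returned; when none
#' exist the returned (empty) set is flagged `"excluded: breast too small"`.
#'
#' @param diff a [DifferenceVolume-class].
#' @param n number of patches requested.
#' @param p patch side in pixels (default 64).
#' @param seed integer seed for the sampler.
#' @param backgroundLimit maximum tolerated background pixels per patch
#'   (default 50).
#' @return a [PatchSet-class] with label `"normal"`.
#' @export
extractRandomPatches <- function(diff, n, p = 64, seed = 1L, backgroundLimit = 50) {
  d <- dim(diff@values)
  if (p > d[2] || p > d[3])
    stop(sprintf("patch side %d exceeds in-plane extent %dx%d", p, d[2], d[3]))
  cand <- NULL
  for (z in seq_len(d[1])) {
    cs <- eligibleCentersSlice(diff@mask[z, , ], p, backgroundLimit)
    if (nrow(cs) > 0) cand <- rbind(cand, cbind(z, cs))
  }
  if (is.null(cand) || nrow(cand) == 0) {
    return(newPatchSet(p, numeric(0), numeric(0), character(0), numeric(0),
                       diff, reason = "excluded: breast too small"))
  }
  set.seed(seed)
  take <- if (nrow(cand) <= n) seq_len(nrow(cand)) else sample.int(nrow(cand), n)
  cand <- cand[take, , drop = FALSE]
  pixels <- vapply(seq_len(nrow(cand)),
                   function(i) cutPatch(diff@values, cand[i, 1], cand[i, 2], cand[i, 3], p),
                   matrix(0, p, p))
  newPatchSet(p, pixels, cand[, 1:3] - 1, rep("normal", nrow(cand)),
              cand[, 4], diff)
}

#' Extract patches at the future lesion location
#'
#' Patches centered on lesion-mask voxels of a difference volume from the
#' screening visits preceding lesion emergence. Candidates whose footprint
#' contains more than `backgroundLimit` pixels of background are excluded; the
#' survivors are subsampled to at most `nPerLesion` patches. If every candidate
#' is excluded the subject is flagged
#' `"excluded from patch-level evaluation"`.
#'
#' @param diff a [DifferenceVolume-class].
#' @param lesionMask 3-D binary array marking the future lesion.
#' @param p patch side (default 64).
#' @param nPerLesion patches retained per lesion (default 30, within the
#'   20-40 per subject the extraction is designed for).
#' @param seed sampler seed.
#' @param backgroundLimit maximum background pixels per patch (default 50).
#' @return a [PatchSet-class] with label `"future_lesion"`.
#' @export
extractLesionPatches <- function(diff, lesionMask, p = 64, nPerLesion = 30,
                                 seed = 1L, backgroundLimit = 50) {
  if (sum(lesionMask) == 0) stop("empty lesion mask")
  d <- dim(diff@values)
  if (p > d[2] || p > d[3])
    stop(sprintf("patch side %d exceeds in-plane extent %dx%d", p, d[2], d[3]))
  off <- floor(p / 2)
  cand <- NULL
  for (z in seq_len(d[1])) {
    counts <- backgroundCounts(diff@mask[z, , ], p)
    les <- which(lesionMask[z, , ] == 1, arr.ind = TRUE)
    if (nrow(les) == 0) next
    tlY <- les[, 1] - off; tlX <- les[, 2] - off
    valid <- tlY >= 1 & tlX >= 1 & tlY + p - 1 <= d[2] & tlX + p - 1 <= d[3]
    if (!any(valid)) next
    les <- les[valid, , drop = FALSE]
    nbg <- counts[cbind(les[, 1] - off, les[, 2] - off)]
    keep <- !is.na(nbg) & nbg <= backgroundLimit
    if (any(keep))
      cand <- rbind(cand, cbind(z, les[keep, , drop = FALSE], nbg[keep]))
  }
  if (is.null(cand) || nrow(cand) == 0) {
    return(newPatchSet(p, numeric(0), numeric(0), character(0), numeric(0),
                       diff, reason = "excluded from patch-level evaluation"))
  }
  set.seed(seed)
  take <- if (nrow(cand) <= nPerLesion) seq_len(nrow(cand))
          else sample.int(nrow(cand), nPerLesion)
  cand <- cand[take, , drop = FALSE]
  pixels <- vapply(seq_len(nrow(cand)),
                   function(i) cutPatch(diff@values, cand[i, 1], cand[i, 2], cand[i, 3], p),
                   matrix(0, p, p))
  newPatchSet(p, pixels, cand[, 1:3] - 1, rep("future_lesion", nrow(cand)),
              cand[, 4], diff)
}

#' Training-split intensity statistics for patch normalization
#'
#' Global percentile bounds of pixel intensity over the training patches; the
#' bounds define the affine map onto the model range \[-1, 1\].
#'
#' @param patches a [PatchSet-class], a list of them, or a numeric matrix of
#'   flattened patches.
#' @param probs lower/upper percentile (default 0.5% / 99.5%).
#' @return list with `lower`, `upper`, `probs`.
#' @export
patchNormStats <- function(patches, probs = c(0.005, 0.995)) {
  vals <- patchValues(patches)
  q <- stats::quantile(vals, probs, names = FALSE, type = 7)
  if (q[2] <= q[1]) stop("degenerate intensity statistics: zero range")
  list(lower = q[1], upper = q[2], probs = probs)
}

patchValues <- function(patches) {
  if (is(patches, "PatchSet")) return(as.numeric(patches@pixels))
  if (is.list(patches)) return(unlist(lapply(patches, patchValues)))
  as.numeric(patches)
}

#' Normalize patches to the model range
#'
#' Affine rescaling of pixel values to \[-1, 1\] using training-split bounds;
#' values beyond the bounds are clipped.
#'
#' @param patches a [PatchSet-class] or numeric matrix (rows = patches).
#' @param stats bounds from [patchNormStats()].
#' @return same type as `patches`, with rescaled pixel values.
#' @export
normalizePatch <- function(patches, stats) {
  if (stats$upper <= stats$lower) stop("degenerate intensity statistics: zero range")
  f <- function(x) {
    out <- 2 * (x - stats$lower) / (stats$upper - stats$lower) - 1
    pmin(pmax(out, -1), 1)
  }
  if (is(patches, "PatchSet")) {
    patches@pixels <- array(f(patches@pixels), dim = dim(patches@pixels))
    return(patches)
  }
  m <- f(patches)
  attributes(m) <- attributes(patches)
  m
}
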