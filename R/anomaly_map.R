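#' Sliding-window anomaly map of a difference volume
#'
#' Evaluates the local anomaly score L in a sliding window over the breast
#' tissue of each axial slice. Window top-left corners lie on the stride grid
#' starting at the volume origin; a window is evaluated when its center voxel
#' falls inside the mask. Every voxel's map value is the mean of L over all
#' windows covering it; the number of contributing windows is recorded as
#' coverage. Voxels outside the mask, or covered by no window, are `NA`.
#'
#' @param diff a [DifferenceVolume-class].
#' @param model an [AnomalyModel-class]; windows are normalized with the
#'   model's training statistics before scoring. Ignored when `scoreFun` is
#'   given.
#' @param stride grid spacing in voxels (default 16, quarter-patch overlap at
#'   the default patch side).
#' @param p window side; defaults to the model's patch side.
#' @param scoreFun optional replacement scorer: a function taking the matrix
#'   of raw flattened windows (rows) and the matrix of 0-based window centers
#'   (z, y, x) and returning one score per window. Intended for stubs and
#'   oracle tests.
#' @return an [AnomalyMap-class]; flagged via an error `"no evaluable tissue"`
#'   when the mask admits no window.
#' @export
slidingWindowMap <- function(diff, model = NULL, stride = 16, p = NULL,
                             scoreFun = NULL) {
  if (stride < 1) stop("stride must be >= 1")
  if (is.null(p)) {
    if (is.null(model)) stop("either a model or an explicit window side is required")
    p <- model@patchSide
  }
  d <- dim(diff@values)
  if (p > d[2] || p > d[3])
    stop(sprintf("window side %d exceeds in-plane extent %dx%d", p, d[2], d[3]))
  off <- floor(p / 2)
  tops <- seq(1, d[2] - p + 1, by = stride)
  lefts <- seq(1, d[3] - p + 1, by = stride)

  windows <- NULL
  for (z in seq_len(d[1])) {
    sl <- diff@mask[z, , ]
    for (ty in tops) for (tx in lefts) {
      if (sl[ty + off, tx + off] == 1)
        windows <- rbind(windows, c(z, ty, tx))
    }
  }
  if (is.null(windows))
    stop("no evaluable tissue: mask admits no window on the stride grid")

  X <- t(vapply(seq_len(nrow(windows)), function(i) {
    as.numeric(diff@values[windows[i, 1],
                           windows[i, 2]:(windows[i, 2] + p - 1),
                           windows[i, 3]:(windows[i, 3] + p - 1)])
  }, numeric(p * p)))
  centers0 <- cbind(windows[, 1] - 1, windows[, 2] + off - 1, windows[, 3] + off - 1)
  scores <- if (!is.null(scoreFun)) {
    as.numeric(scoreFun(X, centers0))
  } else {
    anomalyScore(normalizePatch(X, model@normStats), model)$L
  }

  sums <- array(0, dim = d)
  coverage <- array(0L, dim = d)
  for (i in seq_len(nrow(windows))) {
    z <- windows[i, 1]
    ys <- windows[i, 2]:(windows[i, 2] + p - 1)
    xs <- windows[i, 3]:(windows[i, 3] + p - 1)
    sums[z, ys, xs] <- sums[z, ys, xs] + scores[i]
    coverage[z, ys, xs] <- coverage[z, ys, xs] + 1L
  }
  values <- sums / ifelse(coverage > 0, coverage, NA_real_)
  values[diff@mask == 0] <- NA_real_
  coverage[diff@mask == 0] <- 0L
  new("AnomalyMap", values = values, coverage = coverage, mask = diff@mask,
      subjectId = diff@subjectId, visitPair = diff@visitPair)
}

#' Classify voxels of an anomaly map
#'
#' A covered voxel is called anomalous iff its map value is strictly greater
#' than the patch threshold; voxels with undefined map value stay `NA`.
#'
#' @param map an [AnomalyMap-class].
#' @param patchThreshold finite scalar threshold.
#' @return integer array (1 anomalous, 0 normal, `NA` undefined).
#' @export
classifyVoxels <- function(map, patchThreshold) {
  if (!is.finite(patchThreshold)) stop("patchThreshold must be finite")
  out <- array(NA_integer_, dim = dim(map@values))
  def <- !is.na(map@values)
  out[def] <- as.integer(map@values[def] > patchThreshold)
  out
}

#' Examination-level anomaly score
#'
#' The mean over classified breast-tissue voxels: the fraction of covered mask
#' voxels called anomalous, aggregated over all breast tissue in the volume.
#' Lies in \[0, 1\] by construction.
#'
#' @param binaryField classified voxels from [classifyVoxels()] (`NA` =
#'   uncovered).
#' @param map the source [AnomalyMap-class] (provenance and threshold record).
#' @param patchThreshold threshold used for classification.
#' @param scannerPair scanner periods of the two visits.
#' @return an [ExamScore-class].
#' @export
examLevelScore <- function(binaryField, map, patchThreshold,
                           scannerPair = c(2, 2)) {
  vals <- binaryField[!is.na(binaryField)]
  if (length(vals) == 0) stop("no evaluable tissue: zero covered voxels")
  new("ExamScore", score = mean(vals), patchThreshold = patchThreshold,
      nVoxels = length(vals), subjectId = map@subjectId,
      visitPair = map@visitPair, scannerPair = as.numeric(scannerPair))
}

#' Lesion-level detection call
#'
#' A future lesion counts as detected when at least half of the patches
#' covering its location score above the patch threshold; lesions with less
#' than 50% anomalous patches are missed.
#'
#' @param lesionScores numeric vector of local anomaly scores L of the patches
#'   covering the future lesion location.
#' @param patchThreshold deployed patch threshold.
#' @return list with `fraction` (share of anomalous patches) and `detected`
#'   (`fraction >= 0.5`).
#' @export
lesionLevelDetection <- function(lesionScores, patchThreshold) {
  if (length(lesionScores) == 0) stop("no lesion patches supplied")
  fraction <- mean(lesionScores > patchThreshold)
  list(fraction = fraction, detected = fraction >= 0.5)
}
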