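makeVisit <- function(seed = 1, shape = c(2, 32, 32)) {
  cfg <- cohortConfig(nNegative = 1, nPositive = 1, volumeShape = shape,
                      lesionRadiusVox = 3, seed = seed)
  generateSubject(cfg, "negative", subjectSeed = seed)@visits[[1]]
}

test_that("self-registration is identity-equivalent with perfect quality", {
  v <- makeVisit(31)
  reg <- registerFollowup(v$volume, v$volume, v$mask, v$mask)
  expect_false(reg$excluded)
  expect_equal(reg$quality, 1, tolerance = 1e-6)
  expect_equal(as.numeric(reg$transform[1:3, 4]), c(0, 0, 0), tolerance = 0.05)
})

test_that("a known integer translation is recovered within half a voxel", {
  v <- makeVisit(32)
  d <- dim(v$volume)
  moving <- array(0, dim = d)
  # moving(y, x) = fixed(y + 2, x - 1): true target-to-source map is (-2, +1)
  moving[, 1:(d[2] - 2), 2:d[3]] <- v$volume[, 3:d[2], 1:(d[3] - 1)]
  reg <- registerFollowup(moving, v$volume, v$mask, v$mask, affine = FALSE)
  expect_lt(abs(reg$transform[2, 4] - (-2)), 0.5)
  expect_lt(abs(reg$transform[3, 4] - 1), 0.5)
  expect_gt(reg$quality, 0.9)
})

test_that("uncorrelated volumes are flagged as misregistered", {
  set.seed(4)
  a <- array(rnorm(2 * 24 * 24), dim = c(2, 24, 24))
  b <- array(rnorm(2 * 24 * 24), dim = c(2, 24, 24))
  m <- array(1L, dim = dim(a))
  reg <- registerFollowup(a, b, m, m, affine = FALSE, maxShift = c(0, 2, 2))
  expect_true(reg$excluded)
  expect_match(reg$reason, "misregistration")
  expect_error(registerFollowup(a, b[, 1:20, ], m, m), "shape mismatch")
})

test_that("segmentation handles degenerate, passthrough and two-level inputs", {
  zeros <- array(0, dim = c(2, 20, 20))
  seg <- segmentBreast(zeros)
  expect_true(seg$excluded)
  expect_match(seg$reason, "segmentation")

  v <- makeVisit(33, shape = c(2, 24, 24))
  seg <- segmentBreast(v$volume, passthroughMask = v$mask)
  expect_false(seg$excluded)
  expect_equal(sum(seg$mask != v$mask), 0)

  # bright block on dark background: Otsu must recover the block
  vol <- array(0, dim = c(1, 30, 30))
  vol[1, 8:22, 10:24] <- 1
  seg <- segmentBreast(vol, closingSize = 3)
  expect_false(seg$excluded)
  expect_equal(sum(seg$mask[1, 8:22, 10:24] == 0), 0)
  expect_equal(sum(seg$mask) , 15 * 15)
})

test_that("difference volumes obey the subtraction identities", {
  a <- array(0, dim = c(1, 6, 6)); a[1, 2, 3] <- 5
  b <- array(0, dim = c(1, 6, 6)); b[1, 2, 3] <- 3
  m <- array(1L, dim = dim(a))
  dv <- computeDifference(a, b, m, m)
  expect_equal(diffValues(dv)[1, 2, 3], 2)

  v1 <- makeVisit(34)
  v2 <- makeVisit(35)
  dij <- computeDifference(v2$volume, v1$volume, v2$mask, v1$mask)
  dji <- computeDifference(v1$volume, v2$volume, v1$mask, v2$mask)
  expect_equal(diffValues(dij), -diffValues(dji))
  dself <- computeDifference(v1$volume, v1$volume, v1$mask, v1$mask)
  expect_equal(max(abs(diffValues(dself))), 0)
  expect_error(computeDifference(a, array(0, dim = c(1, 6, 5)), m, m),
               "shape mismatch")
  # mask is the intersection
  m2 <- m; m2[1, 1, ] <- 0L
  expect_equal(sum(diffMask(computeDifference(a, b, m, m2))), sum(m2))
})

test_that("random patch extraction honours placement and background rules", {
  # mask covering a whole 64x64 slice admits exactly one 64-patch center
  vals <- array(rnorm(64 * 64), dim = c(1, 64, 64))
  dv <- toyDiff(vals)
  ps <- extractRandomPatches(dv, n = 5, p = 64, seed = 1)
  expect_equal(nrow(patchCenters(ps)), 1)
  expect_equal(unname(patchCenters(ps)[1, ]), c(0, 32, 32))
  expect_equal(patchMatrix(ps)[1, ], as.numeric(vals[1, , ]))

  # empty mask is flagged
  dvEmpty <- toyDiff(vals, mask = array(0L, dim = dim(vals)))
  psE <- extractRandomPatches(dvEmpty, n = 3, p = 16, seed = 1)
  expect_equal(nrow(patchCenters(psE)), 0)
  expect_match(psE@reason, "breast too small")

  # determinism and the background limit, over random masks
  for (i in 1:5) {
    set.seed(i)
    mask <- array(as.integer(runif(32 * 32) > 0.3), dim = c(1, 32, 32))
    dvR <- toyDiff(array(rnorm(32 * 32), dim = c(1, 32, 32)), mask = mask)
    p1 <- extractRandomPatches(dvR, n = 10, p = 8, seed = 99, backgroundLimit = 20)
    p2 <- extractRandomPatches(dvR, n = 10, p = 8, seed = 99, backgroundLimit = 20)
    expect_identical(patchCenters(p1), patchCenters(p2))
    if (nrow(patchCenters(p1)) > 0) {
      expect_true(all(p1@nBackground <= 20))
      # recount background directly from the mask
      for (j in seq_len(nrow(patchCenters(p1)))) {
        ctr <- patchCenters(p1)[j, ] + 1
        ys <- (ctr[2] - 4):(ctr[2] + 3); xs <- (ctr[3] - 4):(ctr[3] + 3)
        expect_equal(sum(mask[ctr[1], ys, xs] == 0), p1@nBackground[j])
      }
    }
  }
  expect_error(extractRandomPatches(toyDiff(vals), n = 1, p = 100), "exceeds")
})

test_that("lesion patches follow the 50-background-pixel boundary exactly", {
  d <- c(1, 24, 24)
  vals <- array(rnorm(prod(d)), dim = d)
  lesion <- array(0L, dim = d); lesion[1, 12, 12] <- 1L
  baseMask <- array(1L, dim = d)

  # footprint of the single candidate patch (p = 16, center (12,12)): rows/cols 4..19
  holes <- function(k) {
    m <- baseMask
    idx <- arrayInd(seq_len(k), c(16, 16))
    m[1, 4:19, 4:19][idx] <- 0L
    m
  }
  dv50 <- toyDiff(vals, mask = holes(50))
  ps50 <- extractLesionPatches(dv50, lesion, p = 16, seed = 1)
  expect_equal(nrow(patchCenters(ps50)), 1)
  expect_equal(ps50@nBackground, 50)
  expect_equal(patchLabels(ps50), "future_lesion")

  dv51 <- toyDiff(vals, mask = holes(51))
  ps51 <- extractLesionPatches(dv51, lesion, p = 16, seed = 1)
  expect_equal(nrow(patchCenters(ps51)), 0)
  expect_match(ps51@reason, "excluded from patch-level evaluation")

  # lesion deep inside a full mask: all candidates retained, zero background
  lesion2 <- array(0L, dim = d); lesion2[1, 11:13, 11:13] <- 1L
  psAll <- extractLesionPatches(toyDiff(vals), lesion2, p = 16, nPerLesion = 50, seed = 1)
  expect_equal(nrow(patchCenters(psAll)), 9)
  expect_true(all(psAll@nBackground == 0))
  expect_error(extractLesionPatches(toyDiff(vals), array(0L, dim = d), p = 16),
               "empty lesion mask")
})

test_that("patch normalization maps the training bounds onto [-1, 1]", {
  st <- list(lower = -2, upper = 4)
  x <- matrix(c(-2, 4, 1, -5, 9), nrow = 1)
  out <- normalizePatch(x, st)
  expect_equal(as.numeric(out), c(-1, 1, 0, -1, 1))
  # symmetric bounds keep zero fixed
  expect_equal(as.numeric(normalizePatch(matrix(0), list(lower = -3, upper = 3))), 0)
  expect_error(normalizePatch(x, list(lower = 2, upper = 2)), "zero range")
  expect_error(patchNormStats(matrix(1, 3, 3)), "zero range")
  # stats come from the pooled pixel distribution
  st2 <- patchNormStats(matrix(seq(0, 1, length.out = 1001), nrow = 1),
                        probs = c(0, 1))
  expect_equal(st2$lower, 0)
  expect_equal(st2$upper, 1)
})
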