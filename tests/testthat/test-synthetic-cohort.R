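test_that("subject generation is deterministic and respects series invariants", {
  cfg <- cohortConfig(nNegative = 4, nPositive = 2, volumeShape = c(2, 40, 40),
                      lesionRadiusVox = 3, seed = 5)
  s1 <- generateSubject(cfg, "positive", subjectSeed = 42)
  s2 <- generateSubject(cfg, "positive", subjectSeed = 42)
  expect_identical(s1@visits, s2@visits)
  expect_identical(s1@lesionMask, s2@lesionMask)

  grades <- vapply(s1@visits, `[[`, numeric(1), "grade")
  expect_true(all(grades[1:2] == 1))
  expect_gt(grades[3], 1)
  # lesion strictly inside the breast mask
  expect_true(all(s1@visits[[1]]$mask[s1@lesionMask == 1] == 1))
  expect_gt(sum(s1@lesionMask), 0)

  neg <- generateSubject(cfg, "negative", subjectSeed = 43)
  expect_null(neg@lesionMask)
  expect_true(all(vapply(neg@visits, `[[`, numeric(1), "grade") == 1))

  s3 <- generateSubject(cfg, "positive", subjectSeed = 43)
  expect_false(identical(s1@visits[[1]]$volume, s3@visits[[1]]$volume))
})

test_that("with every change source disabled inter-visit differences vanish", {
  cfg <- cohortConfig(nNegative = 1, nPositive = 1, volumeShape = c(2, 30, 30),
                      driftSigma = 0, deformAmp = 0, noiseSigma = 0,
                      lesionContrast = 0, precursorContrast = 0,
                      lesionRadiusVox = 3, scannerShiftProb = 0, seed = 1)
  for (cohort in c("negative", "positive")) {
    s <- generateSubject(cfg, cohort, subjectSeed = 9)
    for (dv in subjectDifferences(s))
      expect_equal(max(abs(diffValues(dv))), 0)
  }
})

test_that("difference signal inside the lesion footprint grows with precursor contrast", {
  means <- vapply(c(0, 0.4, 0.8), function(pc) {
    cfg <- cohortConfig(nNegative = 1, nPositive = 1, volumeShape = c(2, 40, 40),
                        precursorContrast = pc, lesionContrast = 1,
                        deformAmp = 0.2, driftSigma = 0.02,
                        scannerShiftProb = 0, lesionRadiusVox = 3, seed = 2)
    s <- generateSubject(cfg, "positive", subjectSeed = 11)
    dv <- subjectDifferences(s)[[1]]
    mean(abs(diffValues(dv)[s@lesionMask == 1]))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
  expect_gt(means[3], means[1])
})

test_that("zero-contrast positive subjects are indistinguishable from negatives", {
  cfg <- cohortConfig(nNegative = 2, nPositive = 2, volumeShape = c(2, 40, 40),
                      precursorContrast = 0, lesionContrast = 0,
                      lesionRadiusVox = 3, scannerShiftProb = 0, seed = 3)
  patchMeans <- function(cohort, seedBase) {
    out <- numeric(0)
    for (i in 1:4) {
      s <- generateSubject(cfg, cohort, subjectSeed = seedBase + i)
      dv <- subjectDifferences(s)[[1]]
      ps <- extractRandomPatches(dv, 30, p = 16, seed = i)
      out <- c(out, rowMeans(patchMatrix(ps)))
    }
    out
  }
  pv <- t.test(patchMeans("positive", 100), patchMeans("negative", 200))$p.value
  expect_gt(pv, 0.01)
})

test_that("cohort serialization writes a manifest that partitions subjects", {
  dir <- file.path(tempdir(), "anodiff-cohort-test")
  cfg <- cohortConfig(nNegative = 8, nPositive = 4, volumeShape = c(2, 30, 30),
                      lesionRadiusVox = 3, seed = 21)
  man <- generateCohort(cfg, dir, overwrite = TRUE)
  expect_equal(length(unique(man$subject_id)), 12)
  expect_equal(nrow(man), 12 * 3)
  perSubject <- man[!duplicated(man$subject_id), ]
  expect_true(all(table(perSubject$subject_id) == 1))
  expect_setequal(unique(perSubject$split),
                  intersect(c("train", "validation", "test"), perSubject$split))
  # negatives span all three splits, positives never reach training
  expect_true(all(perSubject$split[perSubject$cohort == "positive"] != "train"))
  # round trip: volumes on disk reload to the generated series
  s <- loadSubjectSeries(man, perSubject$subject_id[1], dir)
  expect_s4_class(s, "SubjectSeries")
  expect_equal(dim(s@visits[[1]]$volume), c(2, 30, 30))
  # refusal to overwrite silently
  expect_error(generateCohort(cfg, dir), "overwrite")
})

test_that("period-1 assignment frequency matches the configured probability", {
  cfg <- cohortConfig(nNegative = 2, nPositive = 1, volumeShape = c(1, 24, 24),
                      lesionRadiusVox = 3, scannerShiftProb = 0.5, seed = 8)
  n <- 200
  flags <- vapply(seq_len(n), function(i) {
    s <- generateSubject(cfg, "negative", subjectSeed = 3000 + i)
    s@visits[[1]]$scannerPeriod == 1
  }, logical(1))
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(sum(flags), ci[1])
  expect_lte(sum(flags), ci[2])
})

test_that("invalid configurations are rejected with named violations", {
  expect_error(generateSubject(cohortConfig(nVisits = 2), "negative", 1),
               "nVisits")
  expect_error(cohortConfig(noiseSigma = -1), "noiseSigma")
  expect_error(cohortConfig(precursorContrast = 2, lesionContrast = 1),
               "precursorContrast")
  # volume too small for the lesion names the offending axis
  expect_error(cohortConfig(volumeShape = c(2, 10, 40), lesionRadiusVox = 5),
               "volumeShape\\[2\\]")
})
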