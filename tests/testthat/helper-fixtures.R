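# Shared fixtures. Expensive artifacts (the demonstration pipeline run and
# the null-configuration model) are built once per test session and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

# Full demonstration run at the calibrated desk-scale study conditions.
getDemoRun <- function() {
  cached("demoRun", function() {
    dir <- file.path(tempdir(), "anodiff-demo-run")
    report <- runPipeline(demoRunConfig(seed = 42), dir, overwrite = TRUE)
    list(dir = dir, report = report,
         model = loadAnomalyModel(file.path(dir, "model.rds")),
         patchScores = read.csv(file.path(dir, "patch_scores.csv")),
         examScores = read.csv(file.path(dir, "exam_scores.csv")))
  })
}

# Null configuration: identical to the demo conditions but with zero lesion
# and precursor contrast, smaller grid, used for type-I-error calibration.
nullCohortConfig <- function(nNegative, nPositive, seed) {
  cohortConfig(nNegative = nNegative, nPositive = nPositive, nVisits = 3,
               volumeShape = c(2, 32, 32), textureCorr = 3, deformAmp = 0.6,
               lesionRadiusVox = 3, precursorContrast = 0, lesionContrast = 0,
               scannerShiftProb = 0.3, seed = seed)
}

getNullModel <- function() {
  cached("nullModel", function() {
    cc <- nullCohortConfig(12, 4, seed = 77)
    sets <- list()
    for (i in 1:8) {
      s <- generateSubject(cc, "negative", subjectSeed = deriveSeed(77, "train", i))
      for (dv in subjectDifferences(s))
        sets[[length(sets) + 1]] <- extractRandomPatches(dv, 40, p = 16, seed = i)
    }
    st <- patchNormStats(sets)
    Xtr <- normalizePatch(do.call(rbind, lapply(sets, patchMatrix)), st)
    gc <- ganConfig(latentDim = 16, hidden = 64, batchSize = 64, ganSteps = 100,
                    criticSteps = 5, encoderSteps = 200, lr = 1e-3)
    gan <- trainWGAN(Xtr, gc, seed = 11)
    enc <- trainEncoder(Xtr, gan$G, gan$D, gc, seed = 12)
    model <- anomalyModel(gan$G, gan$D, enc$E, patchSide = 16, normStats = st,
                          k = 0.1)
    list(model = model, trainScores = anomalyScore(Xtr, model)$L, config = gc)
  })
}

# Tiny end-to-end configuration (seconds, not minutes) for determinism and
# plumbing checks: 4 + 2 subjects, 4 x 16 x 16 volumes, 8-pixel patches,
# 50 generator steps.
tinyRunConfig <- function(seed = 7L) {
  runConfig(
    cohort = cohortConfig(nNegative = 6, nPositive = 3, nVisits = 3,
                          volumeShape = c(2, 26, 26), textureCorr = 3,
                          deformAmp = 0.5, lesionRadiusVox = 3,
                          precursorContrast = 0.5, lesionContrast = 1.0,
                          scannerShiftProb = 0.3, seed = seed),
    patchSide = 8, stride = 6, registrationFloor = 0.75,
    patchesPerDiff = 25, lesionPatchesPerSubject = 15,
    gan = ganConfig(latentDim = 8, hidden = 32, batchSize = 32, ganSteps = 50,
                    criticSteps = 5, encoderSteps = 80, lr = 1e-3),
    nPerGroup = 32, nReplicates = 5,
    seed = seed)
}

getTinyRun <- function() {
  cached("tinyRun", function() {
    dir <- file.path(tempdir(), "anodiff-tiny-run")
    report <- runPipeline(tinyRunConfig(), dir, overwrite = TRUE)
    list(dir = dir, report = report)
  })
}

# A difference volume wrapped around explicit values and mask.
toyDiff <- function(values, mask = NULL, visitPair = c(2, 1)) {
  if (is.null(mask)) mask <- array(1L, dim = dim(values))
  computeDifference(values, array(0, dim = dim(values)), mask, mask,
                    visitPair = visitPair, subjectId = "toy")
}

# Model crafted so that L_R and L_D take chosen values on unit-power patches:
# G(E(x)) = 0 gives L_R = mean(x^2); critic features sqrt(featGain) * x give
# L_D = featGain * mean(x^2).
craftedModel <- function(p, featGain = 2, k = 0.1) {
  d <- p * p
  lin <- function(W) list(W = W, b = matrix(0, 1, ncol(W)), act = "linear")
  G <- list(layers = list(lin(matrix(0, d, d))), sizes = c(d, d))
  E <- list(layers = list(lin(diag(d))), sizes = c(d, d))
  D <- list(layers = list(lin(diag(d)), lin(sqrt(featGain) * diag(d)),
                          lin(matrix(0, d, 1))),
            sizes = c(d, d, d, 1))
  anomalyModel(G, D, E, patchSide = p, k = k)
}
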