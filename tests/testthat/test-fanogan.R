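test_that("the anomaly score is the weighted sum of residual and critic terms", {
  p <- 4
  # crafted model: G(E(x)) = 0 and f scaled so L_R = 1, L_D = 2 on unit-power x
  m <- craftedModel(p, featGain = 2, k = 0.1)
  x <- matrix(rep(c(1, -1), length.out = p * p), nrow = 1)   # mean square 1
  sc <- anomalyScore(x, m)
  expect_equal(sc$L_R, 1)
  expect_equal(sc$L_D, 2)
  expect_equal(sc$L, 1.2)
  # the identity L = L_R + k L_D holds exactly for arbitrary weights
  set.seed(3)
  rnd <- trainWGAN(matrix(rnorm(40 * p * p, sd = 0.1), 40),
                   ganConfig(latentDim = 4, hidden = 8, batchSize = 8,
                             ganSteps = 2, criticSteps = 1, encoderSteps = 0),
                   seed = 1)
  enc <- trainEncoder(matrix(rnorm(40 * p * p, sd = 0.1), 40), rnd$G, rnd$D,
                      ganConfig(latentDim = 4, hidden = 8, batchSize = 8,
                                encoderSteps = 0), seed = 2)
  mdl <- anomalyModel(rnd$G, rnd$D, enc$E, patchSide = p, k = 0.1)
  X <- matrix(rnorm(6 * p * p), 6)
  sc <- anomalyScore(X, mdl)
  expect_equal(sc$L, sc$L_R + 0.1 * sc$L_D)
  expect_true(all(sc$L_R >= 0 & sc$L_D >= 0))
})

test_that("a perfect-reconstruction stub scores exactly zero", {
  m <- identityStubModel(6)
  X <- matrix(rnorm(5 * 36), 5)
  expect_equal(reconstructPatches(X, m), X)
  sc <- anomalyScore(X, m)
  expect_equal(sc$L_R, rep(0, 5))
  expect_equal(sc$L_D, rep(0, 5))
  expect_equal(sc$L, rep(0, 5))
})

test_that("the score is monotone in k and invariant to batch composition", {
  p <- 4
  m <- craftedModel(p, featGain = 2, k = 0.1)
  set.seed(8)
  X <- matrix(rnorm(10 * p * p), 10)
  ks <- c(0, 0.05, 0.1, 0.5, 2)
  Ls <- sapply(ks, function(k) anomalyScore(X, m, k = k)$L)
  for (i in 1:10) expect_true(all(diff(Ls[i, ]) >= 0))
  expect_true(all(anomalyScore(X, m, k = 0.5)$L > anomalyScore(X, m, k = 0.1)$L))

  # permuting the batch permutes the scores identically (no cross-talk)
  perm <- sample(10)
  sc1 <- anomalyScore(X, m)
  sc2 <- anomalyScore(X[perm, ], m)
  expect_equal(sc2$L, sc1$L[perm])
  # scoring one patch alone equals scoring it inside a batch
  expect_equal(anomalyScore(X[3, , drop = FALSE], m)$L, sc1$L[3])
  expect_error(anomalyScore(matrix(0, 2, 9), m), "does not match")
})

test_that("training is deterministic under a fixed seed", {
  set.seed(99)
  X <- matrix(rnorm(80 * 16, sd = 0.3), 80)
  gc <- ganConfig(latentDim = 4, hidden = 8, batchSize = 16, ganSteps = 5,
                  criticSteps = 2, encoderSteps = 5)
  a <- trainWGAN(X, gc, seed = 31)
  b <- trainWGAN(X, gc, seed = 31)
  expect_identical(a$G, b$G)
  expect_identical(a$D, b$D)
  ea <- trainEncoder(X, a$G, a$D, gc, seed = 7)
  eb <- trainEncoder(X, a$G, a$D, gc, seed = 7)
  expect_identical(ea$E, eb$E)
  c <- trainWGAN(X, gc, seed = 32)
  expect_false(identical(a$G, c$G))
  expect_error(trainWGAN(X[1:4, ], gc), "fewer patches")
})

test_that("the hand-derived gradient-penalty gradient matches finite differences", {
  set.seed(12)
  D <- anodiff:::mlpInit(c(6, 5, 4, 1), c("lrelu", "lrelu", "linear"))
  X <- matrix(rnorm(3 * 6), 3)
  gp <- anodiff:::criticGradPenalty(D, X)
  eps <- 1e-6
  for (li in 1:3) {
    W <- D$layers[[li]]$W
    for (idx in sample(length(W), min(4, length(W)))) {
      Dp <- D; Dp$layers[[li]]$W[idx] <- W[idx] + eps
      Dm <- D; Dm$layers[[li]]$W[idx] <- W[idx] - eps
      num <- (anodiff:::criticGradPenalty(Dp, X)$penalty -
                anodiff:::criticGradPenalty(Dm, X)$penalty) / (2 * eps)
      expect_lt(abs(num - gp$grads[[li]]$W[idx]), 1e-6)
    }
  }
})

test_that("training on a degenerate all-zero distribution collapses the generator", {
  X <- matrix(0, 64, 16)
  gc <- ganConfig(latentDim = 4, hidden = 16, batchSize = 32, ganSteps = 300,
                  criticSteps = 2, encoderSteps = 0, lr = 2e-3)
  gan <- trainWGAN(X, gc, seed = 5)
  set.seed(5)
  Z <- matrix(rnorm(50 * 4), 50)
  samples <- anodiff:::mlpForward(gan$G, Z)$out
  expect_lt(mean(abs(samples)), 0.1)
  expect_true(all(is.finite(gan$log$critic_loss)))
})

test_that("the trained critic and encoder behave like the method requires", {
  fit <- getNullModel()     # WGAN + encoder trained on normal synthetic patches
  m <- fit$model
  p <- m@patchSide
  # held-out normal patches from the same null configuration
  s <- generateSubject(nullCohortConfig(12, 4, seed = 77), "negative",
                       subjectSeed = deriveSeed(77, "heldout", 1))
  dv <- subjectDifferences(s)[[1]]
  ps <- extractRandomPatches(dv, 60, p = p, seed = 500)
  Xn <- normalizePatch(patchMatrix(ps), m@normStats)
  set.seed(41)
  Xu <- matrix(runif(60 * p * p, -1, 1), 60)
  # critic ranks in-distribution patches above uniform noise
  dNorm <- anodiff:::mlpForward(m@D, Xn)$out
  dNoise <- anodiff:::mlpForward(m@D, Xu)$out
  expect_gt(mean(dNorm), mean(dNoise))
  # encoder inverts the generator better than it fits arbitrary noise
  set.seed(42)
  z0 <- matrix(rnorm(30 * m@latentDim), 30)
  xg <- anodiff:::mlpForward(m@G, z0)$out
  errG <- rowMeans((reconstructPatches(xg, m) - xg)^2)
  errU <- rowMeans((reconstructPatches(Xu[1:30, ], m) - Xu[1:30, ])^2)
  expect_lt(mean(errG), mean(errU))
})

test_that("an untrained encoder still supports the scoring path", {
  set.seed(6)
  X <- matrix(rnorm(40 * 16, sd = 0.2), 40)
  gc <- ganConfig(latentDim = 4, hidden = 8, batchSize = 16, ganSteps = 2,
                  criticSteps = 1, encoderSteps = 0)
  gan <- trainWGAN(X, gc, seed = 1)
  enc <- trainEncoder(X, gan$G, gan$D, gc, seed = 2)
  expect_equal(nrow(enc$log), 0)
  m <- anomalyModel(gan$G, gan$D, enc$E, patchSide = 4)
  sc <- anomalyScore(X[1:3, ], m)
  expect_true(all(is.finite(sc$L)))
})

test_that("serialization round-trips scores to full precision", {
  fit <- getNullModel()
  m <- fit$model
  path <- tempfile(fileext = ".rds")
  saveAnomalyModel(m, path)
  m2 <- loadAnomalyModel(path)
  set.seed(9)
  X <- matrix(runif(20 * m@patchSide^2, -1, 1), 20)
  expect_identical(anomalyScore(X, m), anomalyScore(X, m2))
})
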