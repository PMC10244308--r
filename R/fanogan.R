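#' Training configuration for the adversarial anomaly model
#'
#' Wasserstein GAN with gradient penalty (critic with two hidden layers whose
#' penultimate activations serve as the feature map f), followed by an encoder
#' trained with the izif objective: pixel MSE between x and G(E(x)) plus a
#' weighted MSE of the critic features. Networks are dense (multi-layer
#' perceptron) with leaky-ReLU hidden units, a tanh generator output and linear
#' encoder/critic outputs, sized by `hidden` and `latentDim`.
#'
#' @param latentDim dimension of the noise space z (default 128).
#' @param hidden hidden-layer width used across G, D and E.
#' @param batchSize minibatch size.
#' @param ganSteps generator update steps for WGAN training.
#' @param criticSteps critic updates per generator update (default 5).
#' @param gpWeight gradient-penalty weight (default 10).
#' @param encoderSteps encoder update steps.
#' @param lr Adam learning rate (default 1e-4).
#' @param beta1,beta2 Adam moment decays (defaults 0 and 0.9).
#' @param k weighting of the critic-feature term, both in the encoder
#'   objective and the anomaly score L = L_R + k * L_D (default 0.1).
#' @return a list of class `"ganConfig"`.
#' @export
ganConfig <- function(latentDim = 128, hidden = 128, batchSize = 32,
                      ganSteps = 400, criticSteps = 5, gpWeight = 10,
                      encoderSteps = 400, lr = 1e-4, beta1 = 0, beta2 = 0.9,
                      k = 0.1) {
  structure(list(latentDim = latentDim, hidden = hidden, batchSize = batchSize,
                 ganSteps = ganSteps, criticSteps = criticSteps,
                 gpWeight = gpWeight, encoderSteps = encoderSteps, lr = lr,
                 beta1 = beta1, beta2 = beta2, k = k),
            class = "ganConfig")
}

checkPatchesMatrix <- function(patches) {
  X <- if (is(patches, "PatchSet")) patchMatrix(patches) else as.matrix(patches)
  if (!all(is.finite(X))) stop("non-finite patch values")
  X
}

#' Train the Wasserstein GAN of normal inter-visit change
#'
#' Trains generator G and critic D on normalized normal patches from the
#' training split only, with the gradient-penalty objective (critic loss
#' `mean D(fake) - mean D(real) + gp * mean((||grad D(xhat)|| - 1)^2)`,
#' interpolates drawn uniformly between real and fake samples). Deterministic
#' given `seed` (and a fixed BLAS thread count).
#'
#' @param patches normalized patches: a [PatchSet-class] or numeric matrix with
#'   one flattened patch per row, values in \[-1, 1\].
#' @param config a [ganConfig()] list.
#' @param seed integer seed.
#' @return list with `G`, `D` (network lists) and `log` (a `data.frame` of
#'   per-step critic and generator losses).
#' @export
trainWGAN <- function(patches, config = ganConfig(), seed = 1L) {
  X <- checkPatchesMatrix(patches)
  n <- nrow(X); d <- ncol(X)
  if (n < config$batchSize)
    stop(sprintf("fewer patches (%d) than batch size (%d)", n, config$batchSize))
  set.seed(seed)
  G <- mlpInit(c(config$latentDim, config$hidden, d), c("lrelu", "tanh"),
               outScale = 0.5)
  D <- mlpInit(c(d, config$hidden, config$hidden, 1), c("lrelu", "lrelu", "linear"))
  optG <- adamInit(G); optD <- adamInit(D)
  m <- config$batchSize
  log <- data.frame(step = integer(0), critic_loss = numeric(0),
                    gen_loss = numeric(0))
  sampleZ <- function() matrix(stats::rnorm(m * config$latentDim), m)

  for (step in seq_len(config$ganSteps)) {
    cl <- NA_real_
    for (cs in seq_len(config$criticSteps)) {
      real <- X[sample.int(n, m, replace = n < m), , drop = FALSE]
      fake <- mlpForward(G, sampleZ())$out
      fwR <- mlpForward(D, real)
      fwF <- mlpForward(D, fake)
      # loss = mean(D(fake)) - mean(D(real)) + gp * penalty
      gR <- mlpBackward(D, fwR$cache, matrix(-1 / m, m, 1))$grads
      gF <- mlpBackward(D, fwF$cache, matrix(1 / m, m, 1))$grads
      eps <- stats::runif(m)
      Xhat <- eps * real + (1 - eps) * fake
      gp <- criticGradPenalty(D, Xhat)
      grads <- addGrads(addGrads(gR, gF),
                        lapply(gp$grads, function(g)
                          list(W = config$gpWeight * g$W, b = config$gpWeight * g$b)))
      upd <- adamStep(D, optD, grads, config$lr, config$beta1, config$beta2)
      D <- upd$net; optD <- upd$state
      cl <- mean(fwF$out) - mean(fwR$out) + config$gpWeight * gp$penalty
      if (!is.finite(cl)) stop("non-finite critic loss at step ", step)
    }
    Z <- sampleZ()
    fwG <- mlpForward(G, Z)
    fwD <- mlpForward(D, fwG$out)
    gl <- -mean(fwD$out)
    if (!is.finite(gl)) stop("non-finite generator loss at step ", step)
    dFake <- mlpBackward(D, fwD$cache, matrix(-1 / m, m, 1))$dX
    gG <- mlpBackward(G, fwG$cache, dFake)$grads
    upd <- adamStep(G, optG, gG, config$lr, config$beta1, config$beta2)
    G <- upd$net; optG <- upd$state
    log <- rbind(log, data.frame(step = step, critic_loss = cl, gen_loss = gl))
  }
  list(G = G, D = D, log = log)
}

#' Train the encoder mapping patches into the noise space
#'
#' With G and D frozen, E minimizes the izif objective
#' `mean((x - G(E(x)))^2) + k * mean((f(x) - f(G(E(x))))^2)` where f is the
#' critic's penultimate-layer feature map.
#'
#' @param patches normalized normal training patches (matrix or
#'   [PatchSet-class]).
#' @param G,D trained networks from [trainWGAN()].
#' @param config a [ganConfig()] list (uses `encoderSteps`, `batchSize`, `lr`,
#'   `k`).
#' @param seed integer seed.
#' @return list with `E` (network) and `log` (per-step encoder loss). With
#'   `encoderSteps = 0` the freshly initialized encoder is returned untrained.
#' @export
trainEncoder <- function(patches, G, D, config = ganConfig(), seed = 1L) {
  X <- checkPatchesMatrix(patches)
  n <- nrow(X); d <- ncol(X)
  if (n < config$batchSize && config$encoderSteps > 0)
    stop(sprintf("fewer patches (%d) than batch size (%d)", n, config$batchSize))
  set.seed(seed)
  E <- mlpInit(c(d, config$hidden, config$latentDim), c("lrelu", "linear"),
               outScale = 0.5)
  optE <- adamInit(E)
  m <- config$batchSize
  nFeat <- ncol(D$layers[[2]]$W)
  log <- data.frame(step = integer(0), encoder_loss = numeric(0))
  for (step in seq_len(config$encoderSteps)) {
    batch <- X[sample.int(n, m, replace = n < m), , drop = FALSE]
    fwE <- mlpForward(E, batch)
    fwG <- mlpForward(G, fwE$out)
    Y <- fwG$out
    fwFx <- mlpForward(D, batch, upto = 2)
    fwFy <- mlpForward(D, Y, upto = 2)
    resid <- Y - batch
    featResid <- fwFy$out - fwFx$out
    loss <- mean(resid^2) + config$k * mean(featResid^2)
    if (!is.finite(loss)) stop("non-finite encoder loss at step ", step)
    dY <- 2 * resid / length(resid)
    dYfeat <- mlpBackward(D, fwFy$cache,
                          2 * config$k * featResid / length(featResid),
                          upto = 2)$dX
    dG <- mlpBackward(G, fwG$cache, dY + dYfeat)
    gE <- mlpBackward(E, fwE$cache, dG$dX)$grads
    upd <- adamStep(E, optE, gE, config$lr, config$beta1, config$beta2)
    E <- upd$net; optE <- upd$state
    log <- rbind(log, data.frame(step = step, encoder_loss = loss))
  }
  list(E = E, log = log)
}

#' Bundle trained networks into an anomaly model
#'
#' @param G,D,E network lists ([trainWGAN()], [trainEncoder()]).
#' @param patchSide patch side p the networks expect.
#' @param normStats intensity bounds from [patchNormStats()].
#' @param k score weighting (default 0.1).
#' @param trainingConfig,trainingLog optional training records.
#' @return an [AnomalyModel-class].
#' @export
anomalyModel <- function(G, D, E, patchSide, normStats = list(lower = -1, upper = 1),
                         k = 0.1, trainingConfig = list(), trainingLog = data.frame()) {
  new("AnomalyModel", G = G, D = D, E = E,
      latentDim = ncol(E$layers[[length(E$layers)]]$W),
      k = k, patchSide = patchSide, normStats = normStats,
      trainingConfig = trainingConfig, trainingLog = trainingLog)
}

#' Identity stub model for plumbing tests
#'
#' An [AnomalyModel-class] whose encoder and generator compose to the exact
#' identity and whose critic features are identically zero, so every patch
#' scores L_R = L_D = L = 0. Useful for testing score plumbing, sliding-window
#' aggregation and serialization independent of training.
#'
#' @param p patch side.
#' @param k score weighting.
#' @return an [AnomalyModel-class].
#' @export
identityStubModel <- function(p, k = 0.1) {
  d <- p * p
  idLayer <- function(nIn, nOut) list(W = diag(1, nIn, nOut), b = matrix(0, 1, nOut),
                                      act = "linear")
  G <- list(layers = list(idLayer(d, d)), sizes = c(d, d))
  E <- list(layers = list(idLayer(d, d)), sizes = c(d, d))
  D <- list(layers = list(idLayer(d, d),
                          list(W = matrix(0, d, 4), b = matrix(0, 1, 4), act = "linear"),
                          list(W = matrix(0, 4, 1), b = matrix(0, 1, 1), act = "linear")),
            sizes = c(d, d, 4, 1))
  anomalyModel(G, D, E, patchSide = p, k = k)
}

#' Reconstruct patches through the model
#'
#' Computes y = G(E(x)) for each patch; reconstructions are order-preserving
#' and independent across batch members.
#'
#' @param x normalized patches: [PatchSet-class] or matrix (rows = patches).
#' @param model an [AnomalyModel-class].
#' @return matrix of reconstructions, one row per input patch.
#' @export
reconstructPatches <- function(x, model) {
  X <- checkPatchesMatrix(x)
  if (ncol(X) != model@patchSide^2)
    stop(sprintf("patch dimension %d does not match model patch side %d",
                 ncol(X), model@patchSide))
  mlpForward(model@G, mlpForward(model@E, X)$out)$out
}

#' Local anomaly score of patches
#'
#' The residual score L_R is the mean squared pixel residual between x and its
#' reconstruction y = G(E(x)); the discriminator score L_D is the mean squared
#' difference between the critic's intermediate features f(x) and f(y). The
#' local anomaly score is the weighted sum L = L_R + k * L_D with k taken from
#' the model (default 0.1). Means (not sums) make the score independent of
#' patch size.
#'
#' @param x normalized patches: [PatchSet-class] or matrix (rows = patches).
#' @param model an [AnomalyModel-class].
#' @param k optional override of the model's k.
#' @return `data.frame` with columns `L_R`, `L_D`, `L` (one row per patch).
#' @export
anomalyScore <- function(x, model, k = NULL) {
  X <- checkPatchesMatrix(x)
  if (ncol(X) != model@patchSide^2)
    stop(sprintf("patch dimension %d does not match model patch side %d",
                 ncol(X), model@patchSide))
  if (is.null(k)) k <- model@k
  Y <- mlpForward(model@G, mlpForward(model@E, X)$out)$out
  fX <- mlpForward(model@D, X, upto = min(2, length(model@D$layers) - 1))$out
  fY <- mlpForward(model@D, Y, upto = min(2, length(model@D$layers) - 1))$out
  LR <- rowMeans((X - Y)^2)
  LD <- rowMeans((fX - fY)^2)
  out <- data.frame(L_R = LR, L_D = LD, L = LR + k * LD)
  if (!all(is.finite(out$L)))
    stop("non-finite anomaly score for patch index ",
         paste(which(!is.finite(out$L)), collapse = ", "))
  out
}

#' Save / load an anomaly model
#'
#' Serializes the full model (weights, scoring parameters, normalization
#' statistics, training records) to a single archive; loading reproduces
#' scores to full precision.
#'
#' @param model an [AnomalyModel-class].
#' @param path file path.
#' @return `loadAnomalyModel` returns the restored [AnomalyModel-class].
#' @export
saveAnomalyModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveAnomalyModel
#' @export
loadAnomalyModel <- function(path) readRDS(path)
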