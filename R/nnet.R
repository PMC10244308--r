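## Minimal dense-network machinery used by the adversarial anomaly model.
## A network is a list with elements `layers` (each: W d_in x d_out, b 1 x
## d_out, act in {"lrelu", "tanh", "linear"}). All math is plain R matrix
## algebra; batches are rows. Leaky-ReLU slope is fixed at 0.2.

LRELU_SLOPE <- 0.2

mlpInit <- function(sizes, acts, outScale = 1) {
  stopifnot(length(acts) == length(sizes) - 1)
  layers <- vector("list", length(acts))
  for (i in seq_along(acts)) {
    fanIn <- sizes[i]
    sd <- sqrt(2 / fanIn)
    W <- matrix(stats::rnorm(sizes[i] * sizes[i + 1], sd = sd),
                nrow = sizes[i], ncol = sizes[i + 1])
    if (i == length(acts)) W <- W * outScale
    layers[[i]] <- list(W = W, b = matrix(0, 1, sizes[i + 1]), act = acts[i])
  }
  list(layers = layers, sizes = sizes)
}

applyAct <- function(Z, act) {
  switch(act,
         lrelu = ifelse(Z > 0, Z, LRELU_SLOPE * Z),
         tanh = tanh(Z),
         linear = Z)
}

actGrad <- function(Z, A, act) {
  switch(act,
         lrelu = ifelse(Z > 0, 1, LRELU_SLOPE),
         tanh = 1 - A^2,
         linear = matrix(1, nrow(Z), ncol(Z)))
}

## Forward pass; `upto` stops after that many layers (for critic features).
mlpForward <- function(net, X, upto = length(net$layers)) {
  cache <- vector("list", upto)
  A <- X
  for (i in seq_len(upto)) {
    ly <- net$layers[[i]]
    Z <- A %*% ly$W
    Z <- sweep(Z, 2, as.numeric(ly$b), "+")
    Anew <- applyAct(Z, ly$act)
    cache[[i]] <- list(input = A, Z = Z, A = Anew)
    A <- Anew
  }
  list(out = A, cache = cache)
}

## Backward pass from dOut (gradient w.r.t. the output of layer `upto`).
## Returns parameter gradients (zero-filled for layers beyond `upto`) and the
## gradient w.r.t. the input batch.
mlpBackward <- function(net, cache, dOut, upto = length(cache)) {
  grads <- vector("list", length(net$layers))
  dA <- dOut
  for (i in rev(seq_len(upto))) {
    ly <- net$layers[[i]]
    cc <- cache[[i]]
    dZ <- dA * actGrad(cc$Z, cc$A, ly$act)
    grads[[i]] <- list(W = crossprod(cc$input, dZ),
                       b = matrix(colSums(dZ), 1))
    dA <- dZ %*% t(ly$W)
  }
  for (i in seq_along(grads)) {
    if (is.null(grads[[i]]))
      grads[[i]] <- list(W = net$layers[[i]]$W * 0, b = net$layers[[i]]$b * 0)
  }
  list(grads = grads, dX = dA)
}

adamInit <- function(net) {
  list(m = lapply(net$layers, function(l) list(W = l$W * 0, b = l$b * 0)),
       v = lapply(net$layers, function(l) list(W = l$W * 0, b = l$b * 0)),
       t = 0)
}

adamStep <- function(net, state, grads, lr, beta1 = 0, beta2 = 0.9, eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    for (p in c("W", "b")) {
      g <- grads[[i]][[p]]
      state$m[[i]][[p]] <- beta1 * state$m[[i]][[p]] + (1 - beta1) * g
      state$v[[i]][[p]] <- beta2 * state$v[[i]][[p]] + (1 - beta2) * g^2
      mh <- state$m[[i]][[p]] / c1
      vh <- state$v[[i]][[p]] / c2
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(net = net, state = state)
}

addGrads <- function(a, b) {
  for (i in seq_along(a)) for (p in c("W", "b")) a[[i]][[p]] <- a[[i]][[p]] + b[[i]][[p]]
  a
}

## Gradient of the WGAN-GP penalty mean((||grad_x D(xhat)|| - 1)^2) with
## respect to the critic parameters, for a critic with exactly two leaky-ReLU
## hidden layers and a linear output. For piecewise-linear activations the
## activation masks are locally constant, so the input-gradient
##   g_i = W1 (M1_i o (W2 (M2_i o w3)))
## depends on the parameters only through the weight matrices; the chain rule
## below is exact almost everywhere (identical to double backprop through
## ReLU-family networks).
criticGradPenalty <- function(D, Xhat) {
  W1 <- D$layers[[1]]$W; W2 <- D$layers[[2]]$W; W3 <- D$layers[[3]]$W
  m <- nrow(Xhat)
  Z1 <- sweep(Xhat %*% W1, 2, as.numeric(D$layers[[1]]$b), "+")
  M1 <- ifelse(Z1 > 0, 1, LRELU_SLOPE)
  H1 <- applyAct(Z1, "lrelu")
  Z2 <- sweep(H1 %*% W2, 2, as.numeric(D$layers[[2]]$b), "+")
  M2 <- ifelse(Z2 > 0, 1, LRELU_SLOPE)
  U2 <- M2 * matrix(as.numeric(W3), m, ncol(W2), byrow = TRUE)
  U1 <- M1 * (U2 %*% t(W2))
  G <- U1 %*% t(W1)                       # m x d input gradients
  ng <- sqrt(rowSums(G^2))
  penalty <- mean((ng - 1)^2)
  V <- (2 * (ng - 1) / pmax(ng, 1e-12) / m) * G
  T1 <- M1 * (V %*% W1)
  grads <- list(
    list(W = crossprod(V, U1), b = D$layers[[1]]$b * 0),
    list(W = crossprod(T1, U2), b = D$layers[[2]]$b * 0),
    list(W = matrix(colSums(M2 * (T1 %*% W2)), ncol = 1), b = D$layers[[3]]$b * 0))
  list(penalty = penalty, grads = grads)
}
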