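# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: pair counting for the AUC, exhaustive threshold search for
# Youden, a general-purpose likelihood maximizer for the logistic fit, and
# naive window enumeration for the sliding-window map.

oracleAucPairCount <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  wins <- 0
  for (p in pos) for (q in neg) {
    if (p > q) wins <- wins + 1
    else if (p == q) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

oracleYouden <- function(scores, labels) {
  labels <- as.logical(labels)
  v <- sort(unique(scores))
  cand <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, v[length(v)])
  bestJ <- -Inf; bestT <- NA
  for (t in cand) {
    sens <- sum(scores > t & labels) / sum(labels)
    spec <- sum(scores <= t & !labels) / sum(!labels)
    J <- sens + spec - 1
    if (J > bestJ + 1e-12 || (abs(J - bestJ) <= 1e-12 && t > bestT)) {
      bestJ <- J; bestT <- t
    }
  }
  list(threshold = bestT, youden = bestJ)
}

# Logistic log-likelihood maximized with a quasi-Newton optimizer and
# analytic gradient (independent of stats::glm's IRLS).
oracleLogistic <- function(y, score, scanner) {
  X <- cbind(1, score, scanner)
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(b) {
    eta <- as.numeric(X %*% b)
    p <- 1 / (1 + exp(-eta))
    -as.numeric(crossprod(X, y - p))
  }
  fit <- optim(c(0, 0, 0), nll, gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  fit$par
}

# Exhaustive sliding-window enumeration with per-voxel averaging.
oracleWindowMap <- function(values, mask, p, stride, scoreFun) {
  d <- dim(values)
  off <- floor(p / 2)
  acc <- array(0, dim = d)
  cov <- array(0L, dim = d)
  for (z in seq_len(d[1])) {
    for (ty in seq(1, d[2] - p + 1, by = stride)) {
      for (tx in seq(1, d[3] - p + 1, by = stride)) {
        if (mask[z, ty + off, tx + off] != 1) next
        w <- matrix(as.numeric(values[z, ty:(ty + p - 1), tx:(tx + p - 1)]), 1)
        s <- scoreFun(w, matrix(c(z - 1, ty + off - 1, tx + off - 1), 1))
        ys <- ty:(ty + p - 1); xs <- tx:(tx + p - 1)
        acc[z, ys, xs] <- acc[z, ys, xs] + s
        cov[z, ys, xs] <- cov[z, ys, xs] + 1L
      }
    }
  }
  out <- acc / ifelse(cov > 0, cov, NA_real_)
  out[mask == 0] <- NA_real_
  cov[mask == 0] <- 0L
  list(values = out, coverage = cov)
}

randomInstance <- function(n, tie = FALSE) {
  labels <- c(rep(TRUE, ceiling(n / 2)), rep(FALSE, floor(n / 2)))
  scores <- rnorm(n, mean = ifelse(labels, 0.3, 0))
  if (tie) scores <- round(scores, 1)     # force ties
  list(scores = scores, labels = labels)
}


# Score functions injected into the sliding window for oracle tests.
parityScore <- function(X, centers) (centers[, 2] + centers[, 3]) %% 2
hashScore <- function(X, centers) centers[, 1] * 97 + centers[, 2] * 13 + centers[, 3]
meanScore <- function(X, centers) rowMeans(X)

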