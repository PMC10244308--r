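#' Derive a reproducible child seed from a parent seed and string tags
#'
#' A single pipeline seed fans out to per-stage, per-subject seeds via a
#' polynomial rolling hash of the tags, so subject-level results do not depend
#' on the order in which subjects are processed. The result is always a
#' positive value below 2^31.
#'
#' @param seed integer parent seed.
#' @param ... character or numeric tags identifying the stage/subject.
#' @return a single integer seed in `[1, 2^31)`.
#' @export
deriveSeed <- function(seed, ...) {
  tags <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = "|"),
                       character(1)), collapse = "::")
  m <- 2147483629
  acc <- 0
  for (code in utf8ToInt(tags)) acc <- (acc * 31 + code) %% m
  as.integer(((acc + (as.numeric(seed) %% m) * 7919) %% m) + 1)
}

## 1-D Gaussian blur along one array dimension via a dense (normalized) kernel
## matrix; rows renormalized so edges are not darkened. Dense matmul is fine at
## the grid sizes used here.
gaussKernelMatrix <- function(n, sigma) {
  if (sigma <= 0 || n == 1L) return(diag(n))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  K / rowSums(K)
}

blurAlongDim <- function(arr, dim, sigma) {
  d <- dim(arr)
  if (sigma <= 0 || d[dim] == 1L) return(arr)
  K <- gaussKernelMatrix(d[dim], sigma)
  perm <- c(dim, setdiff(seq_along(d), dim))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[dim])
  m <- K %*% m
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

#' Band-limited Gaussian random field
#'
#' White noise smoothed with a separable Gaussian kernel and rescaled to unit
#' standard deviation; the building block for synthetic tissue texture, drift
#' fields and deformation fields.
#'
#' @param shape integer vector (z, y, x).
#' @param corrLength Gaussian smoothing sigma in voxels (applied along y and x;
#'   along z scaled down for thin stacks).
#' @return array of the requested shape with approximately zero mean and unit
#'   standard deviation.
#' @keywords internal
smoothNoiseField <- function(shape, corrLength) {
  arr <- array(stats::rnorm(prod(shape)), dim = shape)
  arr <- blurAlongDim(arr, 1L, min(corrLength, max(shape[1] / 4, 0.5)))
  arr <- blurAlongDim(arr, 2L, corrLength)
  arr <- blurAlongDim(arr, 3L, corrLength)
  s <- stats::sd(arr)
  if (s > 0) arr <- arr / s
  arr - mean(arr)
}

## Trilinear interpolation of `vol` at fractional voxel coordinates.
## zi, yi, xi are equal-length numeric vectors of 1-based indices; coordinates
## outside the grid return `fill`.
trilinearSample <- function(vol, zi, yi, xi, fill = 0) {
  d <- dim(vol)
  out <- rep(fill, length(zi))
  inside <- zi >= 1 & zi <= d[1] & yi >= 1 & yi <= d[2] & xi >= 1 & xi <= d[3]
  if (!any(inside)) return(out)
  zi <- zi[inside]; yi <- yi[inside]; xi <- xi[inside]
  z0 <- pmin(floor(zi), d[1] - 1L); z0 <- pmax(z0, 1)
  y0 <- pmin(floor(yi), d[2] - 1L); y0 <- pmax(y0, 1)
  x0 <- pmin(floor(xi), d[3] - 1L); x0 <- pmax(x0, 1)
  dz <- zi - z0; dy <- yi - y0; dx <- xi - x0
  idx <- function(z, y, x) (x - 1) * d[1] * d[2] + (y - 1) * d[1] + z
  v <- vol
  val <-
    v[idx(z0,     y0,     x0)]     * (1 - dz) * (1 - dy) * (1 - dx) +
    v[idx(z0 + 1, y0,     x0)]     * dz       * (1 - dy) * (1 - dx) +
    v[idx(z0,     y0 + 1, x0)]     * (1 - dz) * dy       * (1 - dx) +
    v[idx(z0,     y0,     x0 + 1)] * (1 - dz) * (1 - dy) * dx       +
    v[idx(z0 + 1, y0 + 1, x0)]     * dz       * dy       * (1 - dx) +
    v[idx(z0 + 1, y0,     x0 + 1)] * dz       * (1 - dy) * dx       +
    v[idx(z0,     y0 + 1, x0 + 1)] * (1 - dz) * dy       * dx       +
    v[idx(z0 + 1, y0 + 1, x0 + 1)] * dz       * dy       * dx
  out[inside] <- val
  out
}

## Resample a volume under an affine map of voxel coordinates:
## source coordinate = A %*% c(z, y, x, 1) for every target voxel.
resampleAffine <- function(vol, A, fill = 0) {
  d <- dim(vol)
  g <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3])))
  src <- cbind(g, 1) %*% t(A[1:3, , drop = FALSE])
  array(trilinearSample(vol, src[, 1], src[, 2], src[, 3], fill = fill), dim = d)
}

## Counts of zero-mask ("background") pixels in every p x p in-plane window of
## a 2-D mask slice, via an integral image. Returns a matrix indexed by window
## top-left (1-based); windows extending past the edge are NA.
backgroundCounts <- function(maskSlice, p) {
  d <- dim(maskSlice)
  out <- matrix(NA_real_, nrow = d[1], ncol = d[2])
  if (d[1] < p || d[2] < p) return(out)
  bg <- 1 - maskSlice
  S <- rbind(0, cbind(0, apply(apply(bg, 2, cumsum), 1, cumsum)))
  S <- t(S)  # S[i+1, j+1] = sum of bg[1:i, 1:j]
  i <- seq_len(d[1] - p + 1)
  j <- seq_len(d[2] - p + 1)
  out[i, j] <- S[i + p, j + p] - S[i, j + p] - S[i + p, j] + S[i, j]
  out
}

## Largest 6-connected component of a 3-D binary array, by iterative minimum-
## label propagation (vectorized over the whole array; converges in O(diameter)
## passes, which is small at the grid sizes used here).
largestComponent3D <- function(mask) {
  d <- dim(mask)
  lab <- array(seq_len(prod(d)), dim = d)
  lab[mask == 0] <- NA_integer_
  shift <- function(a, dm, by) {
    out <- array(NA_integer_, dim = d)
    n <- d[dm]
    if (abs(by) >= n) return(out)
    to <- lapply(d, seq_len)
    from <- lapply(d, seq_len)
    if (by > 0) { to[[dm]] <- seq_len(n - by); from[[dm]] <- seq_len(n - by) + by }
    else        { to[[dm]] <- seq_len(n + by) - by; from[[dm]] <- seq_len(n + by) }
    sub <- do.call(`[`, c(list(a), from, list(drop = FALSE)))
    do.call(`[<-`, c(list(out), to, list(sub)))
  }
  repeat {
    new <- lab
    for (dm in 1:3) for (by in c(-1L, 1L)) {
      nb <- shift(lab, dm, by)
      new <- pmin(new, nb, na.rm = TRUE)
    }
    new[mask == 0] <- NA_integer_
    if (identical(new, lab)) break
    lab <- new
  }
  tab <- table(lab[!is.na(lab)])
  if (length(tab) == 0) return(array(0L, dim = d))
  keep <- as.integer(names(tab)[which.max(tab)])
  out <- array(0L, dim = d)
  out[!is.na(lab) & lab == keep] <- 1L
  out
}

## md5 of an R object via its canonical JSON serialization (used for config
## and report hashes; avoids timestamps and file paths by construction).
md5OfObject <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}
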