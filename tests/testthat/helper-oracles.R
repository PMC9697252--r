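# Independent nested-loop oracles for the windowed filters and small
# utilities shared across test files. These deliberately re-derive every
# quantity from the definitions, step by step, without touching the
# package's vectorized implementations.

oraclePad <- function(im, r) {
  n <- nrow(im); m <- ncol(im)
  im[c(r:1, 1:n, n:(n - r + 1)), c(r:1, 1:m, m:(m - r + 1))]
}

oracleConvolve <- function(im, kern) {
  r <- (nrow(kern) - 1) / 2
  p <- oraclePad(im, r)
  out <- matrix(0, nrow(im), ncol(im))
  for (i in seq_len(nrow(im))) for (j in seq_len(ncol(im))) {
    acc <- 0
    for (a in seq_len(nrow(kern))) for (b in seq_len(ncol(kern)))
      acc <- acc + kern[a, b] * p[i + a - 1, j + b - 1]
    out[i, j] <- acc
  }
  out
}

oracleLaplacian <- function(im) {
  p <- oraclePad(im, 1)
  out <- matrix(0, nrow(im), ncol(im))
  for (i in seq_len(nrow(im))) for (j in seq_len(ncol(im)))
    out[i, j] <- p[i, j + 1] + p[i + 2, j + 1] + p[i + 1, j] +
      p[i + 1, j + 2] - 4 * im[i, j]
  out
}

# direct evaluation of the bilateral (sigmaL = NULL) or trilateral
# weighted mean, pixel by pixel and neighbor by neighbor
oracleRangeMean <- function(im, N, sS, sR, sL = NULL) {
  h <- (N - 1) / 2
  p <- oraclePad(im, h)
  lap <- if (!is.null(sL)) oracleLaplacian(im)
  pl <- if (!is.null(sL)) oraclePad(lap, h)
  out <- matrix(0, nrow(im), ncol(im))
  for (i in seq_len(nrow(im))) for (j in seq_len(ncol(im))) {
    num <- 0; den <- 0
    for (dx in -h:h) for (dy in -h:h) {
      Ir <- p[i + dx + h, j + dy + h]
      w <- exp(-(dx^2 + dy^2) / (2 * sS^2)) *
        exp(-(Ir - im[i, j])^2 / (2 * sR^2))
      if (!is.null(sL))
        w <- w * exp(-(pl[i + dx + h, j + dy + h] - lap[i, j])^2 / (2 * sL^2))
      num <- num + w * Ir
      den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# spatial-only Gaussian window smoothing (the sigmaR -> Inf limit)
oracleSpatialMean <- function(im, N, sS) {
  h <- (N - 1) / 2
  p <- oraclePad(im, h)
  out <- matrix(0, nrow(im), ncol(im))
  for (i in seq_len(nrow(im))) for (j in seq_len(ncol(im))) {
    num <- 0; den <- 0
    for (dx in -h:h) for (dy in -h:h) {
      w <- exp(-(dx^2 + dy^2) / (2 * sS^2))
      num <- num + w * p[i + dx + h, j + dy + h]
      den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# AUC by exhaustive pair counting with half credit for ties
oraclePairAuc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

randomImage <- function(n, m = n, seed) {
  set.seed(seed)
  matrix(runif(n * m), n, m)
}
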