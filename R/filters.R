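## Feature-image generation: Laplacian-of-Gaussian, Gabor, bilateral, and
## the trilateral filter (a bilateral filter with a second Gaussian range
## kernel on differences of Laplacian responses), plus the
## difference-of-trilateral operator. All windowed operations use reflect
## padding; the per-pixel sums are vectorized over window offsets.

#' Construct a feature-image filter specification
#'
#' @param family "log", "gabor", "bilateral", "trilateral" or
#'   "diff_trilateral".
#' @param sigma LoG shape parameter (pixels).
#' @param sigmaX,sigmaY Gabor Gaussian envelope widths (pixels).
#' @param omegaX0,omegaY0 Gabor center frequencies (cycles/pixel).
#' @param windowN odd neighborhood size for bilateral/trilateral.
#' @param sigmaS spatial Gaussian width (pixels).
#' @param sigmaR intensity-range Gaussian width (intensity units; defaults
#'   assume [0, 1] slices).
#' @param sigmaL Laplacian-range Gaussian width (trilateral only).
#' @param k spatial scale factor (> 1) of the difference-of-trilateral.
#' @param gaborOutput "real" (default) or "magnitude" Gabor response.
#' @return A \linkS4class{FilterSpec}.
#' @export
filterSpec <- function(family, sigma = 2, sigmaX = 2, sigmaY = 2,
                       omegaX0 = 0.1, omegaY0 = 0.1, windowN = 7L,
                       sigmaS = 2, sigmaR = 0.1, sigmaL = 0.1,
                       k = sqrt(2), gaborOutput = c("real", "magnitude")) {
  new("FilterSpec", family = family, sigma = sigma, sigmaX = sigmaX,
      sigmaY = sigmaY, omegaX0 = omegaX0, omegaY0 = omegaY0,
      windowN = as.integer(windowN), sigmaS = sigmaS, sigmaR = sigmaR,
      sigmaL = sigmaL, k = k, gaborOutput = match.arg(gaborOutput))
}

## symmetric reflect padding (edge row/col repeated) by r pixels
padReflect <- function(img, r) {
  n <- nrow(img); m <- ncol(img)
  stopifnot(r <= n, r <= m)
  ri <- c(r:1, 1:n, n:(n - r + 1))
  ci <- c(r:1, 1:m, m:(m - r + 1))
  img[ri, ci, drop = FALSE]
}

## correlation of img with kernel (odd square), reflect boundary
convolveReflect <- function(img, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  p <- padReflect(img, r)
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  for (a in seq_len(nrow(kernel))) for (b in seq_len(ncol(kernel))) {
    k <- kernel[a, b]
    if (k != 0)
      out <- out + k * p[(a - 1) + seq_len(n), (b - 1) + seq_len(m)]
  }
  out
}

#' Laplacian-of-Gaussian kernel
#'
#' Samples the closed-form LoG
#' \deqn{-\frac{1}{\pi\sigma^4}\left(1-\frac{x^2+y^2}{2\sigma^2}\right)
#'   e^{-(x^2+y^2)/2\sigma^2}}
#' on the integer offset grid \code{-radius..radius}; radially symmetric,
#' with value \eqn{-1/\pi\sigma^4} at the origin.
#'
#' @param sigma positive shape parameter (pixels).
#' @param radius kernel half-size; default \code{ceiling(3 * sigma)}
#'   captures essentially all of the kernel mass.
#' @return A (2 radius + 1)^2 numeric matrix.
#' @export
logKernel <- function(sigma, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0, radius >= ceiling(3 * sigma))
  off <- seq(-radius, radius)
  r2 <- outer(off^2, off^2, "+")
  -(1 / (pi * sigma^4)) * (1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))
}

#' Complex Gabor kernel
#'
#' Samples \deqn{G(x,y)=\frac{1}{2\pi\sigma_x\sigma_y}
#'   e^{-\frac12(x^2/\sigma_x^2+y^2/\sigma_y^2)}
#'   e^{i2\pi(\omega_{x0}x+\omega_{y0}y)}}
#' on the integer offset grid; \code{Re()} and \code{Im()} give the cosine
#' and sine quadratures. With both frequencies zero the kernel reduces to
#' the plain Gaussian envelope.
#'
#' @param spec a \linkS4class{FilterSpec} of family "gabor".
#' @param radius kernel half-size; default
#'   \code{ceiling(3 * max(sigmaX, sigmaY))}.
#' @return A complex matrix.
#' @export
gaborKernel <- function(spec, radius = NULL) {
  if (is.null(radius)) radius <- ceiling(3 * max(spec@sigmaX, spec@sigmaY))
  off <- seq(-radius, radius)
  x <- matrix(off, length(off), length(off))
  y <- t(x)
  env <- (1 / (2 * pi * spec@sigmaX * spec@sigmaY)) *
    exp(-0.5 * (x^2 / spec@sigmaX^2 + y^2 / spec@sigmaY^2))
  phase <- 2 * pi * (spec@omegaX0 * x + spec@omegaY0 * y)
  env * complex(real = cos(phase), imaginary = sin(phase))
}

asFeatureImage <- function(mat, spec, sourceId) {
  new("FeatureImage", featureData = mat, spec = spec, sourceId = sourceId)
}

#' Apply the Laplacian-of-Gaussian filter to a slice
#'
#' Convolves the image with \code{\link{logKernel}} under reflect boundary
#' handling. The kernel sums to approximately zero, so a constant image
#' maps to approximately zero response.
#'
#' @param image 2D numeric matrix.
#' @param spec a \linkS4class{FilterSpec} of family "log".
#' @param sourceId identifier recorded in the output.
#' @return A \linkS4class{FeatureImage}.
#' @export
applyLog <- function(image, spec = filterSpec("log"), sourceId = "") {
  stopifnot(length(image) > 0)
  asFeatureImage(convolveReflect(image, logKernel(spec@sigma)), spec, sourceId)
}

#' Apply the Gabor filter to a slice
#'
#' Convolves with the real (cosine) part of the complex Gabor kernel by
#' default; \code{gaborOutput = "magnitude"} convolves with both
#' quadratures and returns the modulus.
#'
#' @inheritParams applyLog
#' @param spec a \linkS4class{FilterSpec} of family "gabor".
#' @return A \linkS4class{FeatureImage}.
#' @export
applyGabor <- function(image, spec = filterSpec("gabor"), sourceId = "") {
  stopifnot(length(image) > 0)
  kern <- gaborKernel(spec)
  out <- if (spec@gaborOutput == "magnitude") {
    re <- convolveReflect(image, Re(kern))
    im <- convolveReflect(image, Im(kern))
    sqrt(re^2 + im^2)
  } else {
    convolveReflect(image, Re(kern))
  }
  asFeatureImage(out, spec, sourceId)
}

## shared core of the bilateral/trilateral windowed weighted means.
## lapMap != NULL adds the third (Laplacian-difference) kernel.
windowedRangeMean <- function(image, windowN, sigmaS, sigmaR,
                              sigmaL = NULL, lapMap = NULL) {
  if (!all(is.finite(image))) stop("non-finite input image")
  h <- (windowN - 1L) %/% 2L
  p <- padReflect(image, h)
  pl <- if (!is.null(lapMap)) padReflect(lapMap, h)
  n <- nrow(image); m <- ncol(image)
  num <- matrix(0, n, m); den <- matrix(0, n, m)
  for (dx in -h:h) for (dy in -h:h) {
    nb <- p[(dx + h) + seq_len(n), (dy + h) + seq_len(m)]
    w <- exp(-(dx^2 + dy^2) / (2 * sigmaS^2)) *
      exp(-(nb - image)^2 / (2 * sigmaR^2))
    if (!is.null(lapMap)) {
      nl <- pl[(dx + h) + seq_len(n), (dy + h) + seq_len(m)]
      w <- w * exp(-(nl - lapMap)^2 / (2 * sigmaL^2))
    }
    num <- num + w * nb
    den <- den + w
  }
  num / den
}

#' Edge-preserving bilateral filter
#'
#' Per-pixel weighted mean over an N-by-N window with a spatial Gaussian
#' kernel on pixel distance and a range Gaussian kernel on intensity
#' difference from the center, normalized by the sum of the weights (a
#' constant image is therefore reproduced exactly). As the range width
#' grows the filter tends to plain Gaussian window smoothing.
#'
#' @inheritParams applyLog
#' @param spec a \linkS4class{FilterSpec} of family "bilateral".
#' @return A \linkS4class{FeatureImage}.
#' @export
bilateralFilter <- function(image, spec = filterSpec("bilateral"),
                            sourceId = "") {
  out <- windowedRangeMean(image, spec@windowN, spec@sigmaS, spec@sigmaR)
  asFeatureImage(out, spec, sourceId)
}

## 4-neighbor discrete Laplacian (center -4, cross +1), reflect boundary
discreteLaplacian <- function(image) {
  p <- padReflect(image, 1L)
  n <- nrow(image); m <- ncol(image)
  p[seq_len(n), 1 + seq_len(m)] + p[2 + seq_len(n), 1 + seq_len(m)] +
    p[1 + seq_len(n), seq_len(m)] + p[1 + seq_len(n), 2 + seq_len(m)] -
    4 * image
}

#' Trilateral filter
#'
#' The bilateral filter augmented with a third multiplicative Gaussian
#' range kernel on the difference of discrete Laplacian responses
#' (4-neighbor stencil) between neighbor and center, penalizing
#' gradient-variation mismatch so high-frequency structure is preserved
#' more strongly than by the bilateral filter. The normalization is the
#' sum of the full trilateral weights, so a constant image is reproduced
#' exactly, and as \code{sigmaL} grows the filter reduces to the bilateral
#' filter.
#'
#' @inheritParams applyLog
#' @param spec a \linkS4class{FilterSpec} of family "trilateral".
#' @return A \linkS4class{FeatureImage}.
#' @export
trilateralFilter <- function(image, spec = filterSpec("trilateral"),
                             sourceId = "") {
  lap <- discreteLaplacian(image)
  out <- windowedRangeMean(image, spec@windowN, spec@sigmaS, spec@sigmaR,
                           spec@sigmaL, lap)
  asFeatureImage(out, spec, sourceId)
}

#' Difference-of-trilateral operator
#'
#' Element-wise difference of two trilateral-filtered images computed at
#' spatial scales \code{k * sigmaS} and \code{sigmaS} (same range and
#' Laplacian widths), analogous to a difference-of-Gaussians band-pass.
#'
#' @inheritParams applyLog
#' @param spec a \linkS4class{FilterSpec} of family "diff_trilateral".
#' @return A \linkS4class{FeatureImage}.
#' @export
differenceOfTrilateral <- function(image,
                                   spec = filterSpec("diff_trilateral"),
                                   sourceId = "") {
  lap <- discreteLaplacian(image)
  wide <- windowedRangeMean(image, spec@windowN, spec@k * spec@sigmaS,
                            spec@sigmaR, spec@sigmaL, lap)
  narrow <- windowedRangeMean(image, spec@windowN, spec@sigmaS,
                              spec@sigmaR, spec@sigmaL, lap)
  asFeatureImage(wide - narrow, spec, sourceId)
}

## matrix-in / matrix-out dispatcher used by the training pipeline
applyFilterMatrix <- function(image, spec) {
  switch(spec@family,
    log = convolveReflect(image, logKernel(spec@sigma)),
    gabor = featureData(applyGabor(image, spec)),
    bilateral = windowedRangeMean(image, spec@windowN, spec@sigmaS,
                                  spec@sigmaR),
    trilateral = featureData(trilateralFilter(image, spec)),
    diff_trilateral = featureData(differenceOfTrilateral(image, spec)),
    stop("unknown filter family"))
}

#' Filter every slice of a perspective stack
#'
#' Applies the chosen feature-image filter independently to each slice,
#' preserving slice order and plane indices.
#'
#' @param stack a \linkS4class{PerspectiveStack}.
#' @param spec a \linkS4class{FilterSpec}.
#' @return A \linkS4class{PerspectiveStack} whose slices are the feature
#'   images.
#' @export
filterStack <- function(stack, spec) {
  filtered <- lapply(stack@slices, applyFilterMatrix, spec = spec)
  initialize(stack, slices = filtered)
}
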