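test_that("the LoG kernel matches its closed form", {
  k <- logKernel(1)
  r <- (nrow(k) - 1) / 2
  expect_equal(k[r + 1, r + 1], -1 / pi, tolerance = 1e-14)

  # vanishes on the circle x^2 + y^2 = 2 sigma^2 (offset (1,1) at sigma 1)
  expect_equal(k[r + 2, r + 2], 0, tolerance = 1e-15)

  # radial symmetry: k(x, y) = k(-x, -y) = k(y, x)
  expect_equal(k, k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))])
  expect_equal(k, t(k))

  expect_error(logKernel(-1), "sigma")
})

test_that("the Gabor kernel has the stated quadratures and Gaussian limit", {
  sp <- filterSpec("gabor", sigmaX = 2, sigmaY = 3, omegaX0 = 0.15,
                   omegaY0 = 0.05)
  k <- gaborKernel(sp)
  r <- (nrow(k) - 1) / 2
  expect_equal(Re(k)[r + 1, r + 1], 1 / (2 * pi * 2 * 3), tolerance = 1e-14)
  expect_equal(Im(k)[r + 1, r + 1], 0, tolerance = 1e-14)

  # zero frequency: the kernel is exactly the Gaussian envelope
  sp0 <- filterSpec("gabor", sigmaX = 2, sigmaY = 3, omegaX0 = 0,
                    omegaY0 = 0)
  k0 <- gaborKernel(sp0)
  off <- seq(-r, r)
  x <- matrix(off, length(off), length(off)); y <- t(x)
  gauss <- (1 / (2 * pi * 2 * 3)) * exp(-0.5 * (x^2 / 4 + y^2 / 9))
  expect_equal(Re(k0), gauss, tolerance = 1e-15)
  expect_true(all(Im(k0) == 0))
})

test_that("every filter matches its nested-loop direct evaluation", {
  for (s in 1:20) {
    img9 <- randomImage(9, seed = 5000 + s)
    img7 <- randomImage(7, seed = 6000 + s)

    lsp <- filterSpec("log", sigma = 1)
    expect_equal(featureData(applyLog(img9, lsp)),
                 oracleConvolve(img9, logKernel(1)), tolerance = 1e-10)

    gsp <- filterSpec("gabor", sigmaX = 1.2, sigmaY = 1, omegaX0 = 0.2,
                      omegaY0 = 0.1)
    expect_equal(featureData(applyGabor(img9, gsp)),
                 oracleConvolve(img9, Re(gaborKernel(gsp))),
                 tolerance = 1e-10)

    bsp <- filterSpec("bilateral", windowN = 5, sigmaS = 1.5, sigmaR = 0.2)
    expect_equal(featureData(bilateralFilter(img7, bsp)),
                 oracleRangeMean(img7, 5, 1.5, 0.2), tolerance = 1e-10)

    tsp <- filterSpec("trilateral", windowN = 5, sigmaS = 1.5,
                      sigmaR = 0.2, sigmaL = 0.3)
    expect_equal(featureData(trilateralFilter(img7, tsp)),
                 oracleRangeMean(img7, 5, 1.5, 0.2, 0.3), tolerance = 1e-10)
  }
})

test_that("limit reductions hold numerically", {
  for (s in 1:5) {
    img <- randomImage(12, seed = 7000 + s)

    # trilateral -> bilateral as sigmaL -> Inf
    tri <- trilateralFilter(img, filterSpec("trilateral", windowN = 7,
                                            sigmaS = 2, sigmaR = 0.15,
                                            sigmaL = 1e9))
    bil <- bilateralFilter(img, filterSpec("bilateral", windowN = 7,
                                           sigmaS = 2, sigmaR = 0.15))
    expect_equal(featureData(tri), featureData(bil), tolerance = 1e-6)

    # bilateral -> plain Gaussian window smoothing as sigmaR -> Inf
    wide <- bilateralFilter(img, filterSpec("bilateral", windowN = 7,
                                            sigmaS = 2, sigmaR = 1e9))
    expect_equal(featureData(wide), oracleSpatialMean(img, 7, 2),
                 tolerance = 1e-6)
  }
})

test_that("LoG responds ~zero to constants and tracks smooth-then-Laplacian", {
  const <- matrix(1, 20, 20)
  out <- featureData(applyLog(const, filterSpec("log", sigma = 2)))
  expect_lt(max(abs(out)), 0.01)  # discrete kernel sum is ~ -6e-3

  # Gaussian-smooth then discrete Laplacian approximates the LoG response
  # (discretization of the Laplacian stencil bounds the agreement)
  img <- randomImage(32, seed = 11)
  log2 <- featureData(applyLog(img, filterSpec("log", sigma = 2)))
  off <- -6:6
  r2 <- outer(off^2, off^2, "+")
  gk <- (1 / (2 * pi * 4)) * exp(-r2 / 8)
  twoStep <- oracleLaplacian(oracleConvolve(img, gk))
  interior <- 9:24
  num <- max(abs(log2[interior, interior] - twoStep[interior, interior]))
  expect_lt(num / max(abs(log2[interior, interior])), 0.2)
  expect_gt(cor(as.vector(log2[interior, interior]),
                as.vector(twoStep[interior, interior])), 0.99)
})

test_that("windowed filters are convex combinations and preserve constants", {
  img <- randomImage(15, seed = 77)
  for (fd in list(featureData(bilateralFilter(img)),
                  featureData(trilateralFilter(img)))) {
    expect_identical(dim(fd), dim(img))
    expect_true(all(is.finite(fd)))
    expect_gte(min(fd), min(img))
    expect_lte(max(fd), max(img))
  }
  const <- matrix(0.4, 10, 10)
  expect_equal(featureData(bilateralFilter(const)), const, tolerance = 1e-12)
  expect_equal(featureData(trilateralFilter(const)), const, tolerance = 1e-12)
  expect_error(bilateralFilter(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
})

test_that("difference-of-trilateral is the two-scale difference", {
  img <- randomImage(12, seed = 13)
  sp <- filterSpec("diff_trilateral", windowN = 5, sigmaS = 1.5,
                   sigmaR = 0.2, sigmaL = 0.3, k = sqrt(2))
  dt <- featureData(differenceOfTrilateral(img, sp))
  wide <- oracleRangeMean(img, 5, sqrt(2) * 1.5, 0.2, 0.3)
  narrow <- oracleRangeMean(img, 5, 1.5, 0.2, 0.3)
  expect_equal(dt, wide - narrow, tolerance = 1e-10)

  const <- matrix(0.3, 8, 8)
  expect_equal(featureData(differenceOfTrilateral(const, sp)),
               matrix(0, 8, 8), tolerance = 1e-12)
  expect_error(filterSpec("diff_trilateral", k = 1), "k must be > 1")
})

test_that("stack filtering is slice-wise and order preserving", {
  set.seed(5)
  slices <- lapply(1:6, function(i) matrix(runif(56 * 56), 56, 56))
  st <- new("PerspectiveStack", perspective = "V1", slices = slices,
            sliceIndices = c(1L, 12L, 23L, 34L, 45L, 56L))
  sp <- filterSpec("log", sigma = 2)
  fst <- filterStack(st, sp)
  expect_length(fst@slices, 6)
  expect_identical(fst@sliceIndices, st@sliceIndices)
  for (i in c(1, 4, 6))
    expect_equal(fst@slices[[i]], featureData(applyLog(slices[[i]], sp)))

  constSt <- new("PerspectiveStack", perspective = "V2",
                 slices = lapply(1:6, function(i) matrix(0.2, 20, 20)),
                 sliceIndices = 1:6)
  bst <- filterStack(constSt, filterSpec("bilateral"))
  for (sl in bst@slices) expect_equal(sl, matrix(0.2, 20, 20), tolerance = 1e-12)
})
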