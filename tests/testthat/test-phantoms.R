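test_that("nodule injection is additive, centered and local", {
  vol <- array(0, dim = c(40, 40, 40))
  sp <- rep(1, 3)

  # zero-amplitude blob leaves the volume untouched
  expect_identical(injectNodule(vol, sp, c(20, 20, 20), c(10, 10, 10), 0), vol)

  # the voxel nearest the center gains ~ the peak
  out <- injectNodule(vol, sp, c(20.2, 19.9, 20.1), c(12, 12, 12), 0.7)
  gain <- max(out)
  expect_lt(abs(gain - 0.7), 0.05 * 0.7)

  # voxels outside the 2x-extent box are untouched
  expect_identical(out[1:5, , ], vol[1:5, , ])

  # disjoint injections commute exactly
  a <- c(10, 10, 10); b <- c(30, 30, 30); e <- c(8, 8, 8)
  ab <- injectNodule(injectNodule(vol, sp, a, e, 0.5), sp, b, e, 0.3)
  ba <- injectNodule(injectNodule(vol, sp, b, e, 0.3), sp, a, e, 0.5)
  expect_equal(ab, ba, tolerance = 1e-14)

  expect_error(injectNodule(vol, sp, c(-5, 20, 20), e, 1), "geometry")
})

test_that("distractors are seeded, elongated (tube) and vanish at zero amplitude", {
  vol <- array(0, dim = c(60, 60, 60))
  sp <- rep(1, 3)
  params <- list(centerMm = c(30, 30, 30), peak = 1, widthMm = 4, ratio = 4)

  v1 <- injectDistractor(vol, sp, "tube", params, seed = 5)
  v2 <- injectDistractor(vol, sp, "tube", params, seed = 5)
  expect_identical(v1, v2)

  # principal-axis extent ratio of supra-threshold voxels >= 3
  idx <- which(v1 > 0.5 * max(v1), arr.ind = TRUE)
  pts <- sweep(idx, 2, sp, `*`)
  ev <- eigen(cov(pts))
  proj <- pts %*% ev$vectors
  ranges <- apply(proj, 2, function(x) diff(range(x)))
  expect_gte(max(ranges) / min(ranges), 3)

  v0 <- injectDistractor(vol, sp, "speckle",
                         list(centerMm = c(30, 30, 30), amplitude = 0),
                         seed = 1)
  attr(v0, "extentMm") <- NULL
  expect_identical(v0, vol)

  expect_error(
    injectDistractor(vol, sp, "swirl", params, seed = 1), "configuration")
})

test_that("reader simulation jitters, misses and resamples as configured", {
  obj <- new("GroundTruthObject", kind = "nodule", centerMm = c(20, 20, 20),
             extentMm = c(10, 10, 10), peakIntensity = 0.8,
             readerAnnotations = data.frame())

  # no jitter, no misses: four identical annotations at the true center
  exact <- simulateReaders(obj, 4, 0, 0, seed = 1)
  ann <- exact@readerAnnotations
  expect_equal(nrow(ann), 4)
  expect_true(all(ann$cx_mm == 20 & ann$cy_mm == 20 & ann$cz_mm == 20))

  # jitter magnitude never exceeds the configured bound
  for (s in 1:50) {
    r <- simulateReaders(obj, 4, 2, 0, jitterBoundMm = 2.5, seed = 100 + s)
    a <- r@readerAnnotations
    d <- sqrt((a$cx_mm - 20)^2 + (a$cy_mm - 20)^2 + (a$cz_mm - 20)^2)
    expect_lte(max(d), 2.5)
  }

  # seeded reproducibility
  r1 <- simulateReaders(obj, 4, 1, 0.25, seed = 9)
  r2 <- simulateReaders(obj, 4, 1, 0.25, seed = 9)
  expect_identical(r1@readerAnnotations, r2@readerAnnotations)

  # Monte-Carlo: the first-draw retention count (before the at-least-one
  # resampling guard) has the Binomial(4, 0.5) mean of 2
  counts <- initial <- numeric(4000)
  for (s in seq_len(4000)) {
    r <- simulateReaders(obj, 4, 0, 0.5, seed = s)
    counts[s] <- nrow(r@readerAnnotations)
    initial[s] <- attr(r@readerAnnotations, "initialRetained")
  }
  expect_true(all(counts >= 1))
  m <- mean(initial)
  expect_gt(m, 1.9); expect_lt(m, 2.1)

  expect_error(simulateReaders(obj, 0, 1, 0.2), "nReaders")
  expect_error(simulateReaders(obj, 4, 1, 1.0), "missProb")
})

test_that("generated datasets are balanced, reproducible and in-bounds", {
  ds <- generateDataset(10, 6, "easy", seed = 21)
  kinds <- unlist(lapply(ds$scans, function(sc)
    vapply(sc@objects, function(o) o@kind, character(1))))
  expect_length(kinds, 60)
  expect_lte(abs(sum(kinds == "nodule") - 30), 1)

  ds2 <- generateDataset(10, 6, "easy", seed = 21)
  expect_identical(ds$annotations, ds2$annotations)

  # every annotation center lies inside its scan's physical bounds
  for (sc in ds$scans) {
    b <- dim(sc@volume) * sc@spacingMm
    for (ob in sc@objects) {
      a <- ob@readerAnnotations
      expect_true(all(a$cx_mm >= 0 & a$cx_mm <= b[1] &
                      a$cy_mm >= 0 & a$cy_mm <= b[2] &
                      a$cz_mm >= 0 & a$cz_mm <= b[3]))
    }
  }
})

test_that("the separability dial moves the intensity-threshold oracle", {
  accs <- vapply(1:5, function(s) c(
    easy = intensityThresholdAccuracy(
      generateDataset(4, 4, "easy", seed = 700 + s)$scans),
    hard = intensityThresholdAccuracy(
      generateDataset(4, 4, "hard", seed = 700 + s)$scans)), numeric(2))
  expect_gte(mean(accs["easy", ]), 0.95)
  expect_lte(mean(accs["hard", ]), 0.85)
})
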