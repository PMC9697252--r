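mkAnn <- function(centers, kind = "nodule", ext = 10, scan = "s1") {
  data.frame(scan_id = scan, reader_id = seq_len(nrow(centers)), kind = kind,
             cx_mm = centers[, 1], cy_mm = centers[, 2], cz_mm = centers[, 3],
             ex_mm = ext, ey_mm = ext, ez_mm = ext)
}

mkConsensus <- function(center, kind = "nodule", ext = rep(12, 3),
                        approval = 2L, scan = "s1") {
  new("ConsensusObject", kind = kind, centerMm = center,
      approvalCount = approval, extentMm = ext, sourceScan = scan)
}

test_that("annotation merging clusters by distance and averages centers", {
  # two annotations 1 mm apart under a 5 mm threshold: one object
  ann <- mkAnn(rbind(c(10, 10, 10), c(11, 10, 10)))
  out <- mergeReaderAnnotations(ann, 5)
  expect_length(out, 1)
  expect_equal(out[[1]]@approvalCount, 2L)
  expect_equal(out[[1]]@centerMm, c(10.5, 10, 10))

  # singleton passes through untouched
  one <- mergeReaderAnnotations(mkAnn(rbind(c(3, 4, 5))), 5)
  expect_length(one, 1)
  expect_equal(one[[1]]@approvalCount, 1L)
  expect_equal(one[[1]]@centerMm, c(3, 4, 5))

  # four pairwise-distant annotations stay four objects
  far <- mkAnn(rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0), c(0, 0, 20)))
  expect_length(mergeReaderAnnotations(far, 5), 4)

  # nodule extent: element-wise max of merged extents
  ann$ex_mm <- c(8, 12)
  expect_equal(mergeReaderAnnotations(ann, 5)[[1]]@extentMm[1], 12)

  expect_length(mergeReaderAnnotations(mkAnn(rbind(c(1, 1, 1)))[0, ], 5), 0)
})

test_that("consensus is invariant to annotation row order", {
  set.seed(31)
  centers <- matrix(runif(8 * 3, 0, 50), 8, 3)
  ann <- mkAnn(centers)
  a <- mergeReaderAnnotations(ann, 8)
  b <- mergeReaderAnnotations(ann[sample(8), ], 8)
  key <- function(objs) {
    m <- t(vapply(objs, function(o) c(o@centerMm, o@approvalCount),
                  numeric(4)))
    m[do.call(order, as.data.frame(m)), , drop = FALSE]
  }
  expect_equal(key(a), key(b))
})

test_that("cross-kind conflicts remove both members and only them", {
  nod <- list(mkConsensus(c(10, 10, 10)), mkConsensus(c(40, 40, 40)))
  non <- list(mkConsensus(c(11, 10, 10), "non_nodule"),
              mkConsensus(c(70, 70, 70), "non_nodule"))
  out <- eliminateConflicts(nod, non, 5)
  expect_length(out$nodules, 1)
  expect_length(out$nonNodules, 1)
  expect_equal(out$nodules[[1]]@centerMm, c(40, 40, 40))

  # single close pair empties both lists
  out2 <- eliminateConflicts(list(mkConsensus(c(1, 1, 1))),
                             list(mkConsensus(c(1, 1, 3), "non_nodule")), 5)
  expect_length(out2$nodules, 0)
  expect_length(out2$nonNodules, 0)

  # distant lists and empty lists are untouched
  out3 <- eliminateConflicts(nod, list(), 5)
  expect_length(out3$nodules, 2)
  # conservation: removed + retained = input
  expect_equal(length(out$nodules) + 1L, length(nod))
})

test_that("VOI extraction crops in mm, resamples and normalizes", {
  set.seed(7)
  vol <- array(runif(96^3), dim = c(96, 96, 96))
  cons <- mkConsensus(c(28.8, 28.8, 28.8))

  voi <- extractVoi(vol, cons, cubeMm = 30, outRes = 56,
                    spacingMm = rep(0.6, 3))
  expect_identical(voi@nativeCubeVoxels, rep(50L, 3))
  expect_identical(dim(voi@voiData), rep(56L, 3))
  expect_gte(min(voi@voiData), 0)
  expect_lte(max(voi@voiData), 1)

  # uniform scan maps to the all-zero cube (normalization guard)
  flat <- extractVoi(array(0.5, dim = c(96, 96, 96)), cons, 30, 56,
                     rep(0.6, 3))
  expect_true(all(flat@voiData == 0))

  # spacing 30/56: the native crop is already 56^3 and resampling is
  # the identity; the VOI is the min-max-normalized crop
  sp56 <- rep(30 / 56, 3)
  vol2 <- array(runif(70^3), dim = c(70, 70, 70))
  ctr <- c(35, 35, 35) * sp56[1]
  voi2 <- extractVoi(vol2, mkConsensus(ctr), 30, 56, sp56)
  expect_identical(voi2@nativeCubeVoxels, rep(56L, 3))
  crop <- vol2[8:63, 8:63, 8:63]
  crop <- (crop - min(crop)) / (max(crop) - min(crop))
  expect_equal(voi2@voiData, crop, tolerance = 1e-9)

  expect_error(extractVoi(vol, mkConsensus(c(999, 10, 10)), 30, 56,
                          rep(0.6, 3)), "geometry")
})

test_that("slice selection spans the object at equal intervals", {
  set.seed(3)
  cube <- array(runif(56^3), dim = rep(56, 3))
  full <- new("VolumeOfInterest", voiData = cube, label = "non_nodule",
              consensus = mkConsensus(c(1, 1, 1), "non_nodule",
                                      rep(NA_real_, 3)),
              nativeCubeVoxels = rep(50L, 3))

  # non-nodule: full span, 6 equal-interval planes including endpoints
  st <- selectSlices(full, "V1", 6)
  expect_identical(st@sliceIndices, as.integer(round(seq(1, 56, length.out = 6))))
  expect_identical(st@sliceIndices - 1L, c(0L, 11L, 22L, 33L, 44L, 55L))

  # single slice: the middle plane of the span
  st1 <- selectSlices(full, "V1", 1)
  expect_identical(st1@sliceIndices, as.integer(round((1 + 56) / 2)))

  # nodule span: indices strictly increasing and inside the span
  for (ext in c(6, 10, 18, 29)) {
    nod <- new("VolumeOfInterest", voiData = cube, label = "nodule",
               consensus = mkConsensus(c(1, 1, 1), ext = rep(ext, 3)),
               nativeCubeVoxels = rep(50L, 3))
    idx <- selectSlices(nod, "V2", 6)@sliceIndices
    expect_true(all(diff(idx) > 0))
    half <- (ext / 2) / (30 / 56)
    expect_gte(min(idx), round(28.5 - half))
    expect_lte(max(idx), round(28.5 + half))
  }

  # slices really come from the stated planes of the stated axis
  expect_equal(st@slices[[2]], cube[, , 12])
  expect_equal(selectSlices(full, "V3", 6)@slices[[1]], cube[1, , ])

  # degenerate span repeats boundary planes with a warning
  tiny <- new("VolumeOfInterest", voiData = cube, label = "nodule",
              consensus = mkConsensus(c(1, 1, 1), ext = rep(1, 3)),
              nativeCubeVoxels = rep(50L, 3))
  expect_warning(selectSlices(tiny, "V1", 6), "degenerate")
})

test_that("the stratified split is exact, disjoint and balanced", {
  labs604 <- rep(c("nodule", "non_nodule"), each = 302)
  sp <- splitDataset(labs604, 0.7, seed = 1)
  expect_length(sp$train, 422)
  expect_length(sp$test, 182)

  labs10 <- rep(c("nodule", "non_nodule"), each = 5)
  sp10 <- splitDataset(labs10, 0.7, seed = 1)
  expect_length(sp10$train, 7)
  expect_length(sp10$test, 3)

  for (s in 1:5) {
    set.seed(s)
    labs <- sample(c("nodule", "non_nodule"), 37, replace = TRUE)
    sp <- splitDataset(labs, 0.7, seed = s)
    expect_setequal(c(sp$train, sp$test), seq_along(labs))
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(sp$train, floor(0.7 * 37))
    for (part in sp) {
      n1 <- sum(labs[part] == "nodule")
      expect_lte(abs(n1 - length(part) * sum(labs == "nodule") / 37), 1)
    }
  }
})
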