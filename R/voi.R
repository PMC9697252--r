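## Multi-reader consensus, conflict elimination, physical-unit VOI
## extraction with resolution normalization, and equal-interval slice
## selection per perspective.

## trilinear interpolation at continuous 1-based voxel indices (rows of pts)
trilinearSample <- function(volume, pts) {
  d <- dim(volume)
  pts <- pmin(pmax(pts, 1), matrix(d, nrow(pts), 3, byrow = TRUE))
  f <- floor(pts)
  f <- pmin(f, matrix(d - 1L, nrow(pts), 3, byrow = TRUE))
  w <- pts - f
  i0 <- f[, 1]; j0 <- f[, 2]; k0 <- f[, 3]
  at <- function(i, j, k) volume[cbind(i, j, k)]
  (1 - w[, 1]) * (1 - w[, 2]) * (1 - w[, 3]) * at(i0, j0, k0) +
    w[, 1] * (1 - w[, 2]) * (1 - w[, 3]) * at(i0 + 1, j0, k0) +
    (1 - w[, 1]) * w[, 2] * (1 - w[, 3]) * at(i0, j0 + 1, k0) +
    w[, 1] * w[, 2] * (1 - w[, 3]) * at(i0 + 1, j0 + 1, k0) +
    (1 - w[, 1]) * (1 - w[, 2]) * w[, 3] * at(i0, j0, k0 + 1) +
    w[, 1] * (1 - w[, 2]) * w[, 3] * at(i0 + 1, j0, k0 + 1) +
    (1 - w[, 1]) * w[, 2] * w[, 3] * at(i0, j0 + 1, k0 + 1) +
    w[, 1] * w[, 2] * w[, 3] * at(i0 + 1, j0 + 1, k0 + 1)
}

## union-find single-linkage clustering: merge pairs closer than threshold
singleLinkClusters <- function(centers, threshold) {
  n <- nrow(centers)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (sqrt(sum((centers[i, ] - centers[j, ])^2)) < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Merge same-kind reader annotations into consensus objects
#'
#' Annotations of one scan and one kind whose centers are closer than
#' \code{distanceThresholdMm} are assumed to mark the same object and are
#' merged by single-linkage clustering. Each cluster yields one
#' \linkS4class{ConsensusObject} with the arithmetic-mean center, an
#' approval count equal to the cluster size and, for nodules, the
#' element-wise maximum of the annotated extents. The result does not
#' depend on the row order of the input.
#'
#' @param annotations data.frame with columns \code{kind, cx_mm, cy_mm,
#'   cz_mm} and optionally \code{ex_mm, ey_mm, ez_mm, scan_id}; all rows
#'   must share one scan and one kind.
#' @param distanceThresholdMm positive merge threshold in mm.
#' @return List of \linkS4class{ConsensusObject} (empty list for empty input).
#' @export
mergeReaderAnnotations <- function(annotations, distanceThresholdMm = 5) {
  stopifnot(distanceThresholdMm > 0)
  if (nrow(annotations) == 0L) return(list())
  if (length(unique(annotations$kind)) != 1L)
    stop("all annotations must share one kind")
  if (!is.null(annotations$scan_id) &&
      length(unique(annotations$scan_id)) != 1L)
    stop("all annotations must come from one scan")
  kind <- annotations$kind[1]
  scanId <- if (is.null(annotations$scan_id)) NA_character_ else
    annotations$scan_id[1]
  centers <- as.matrix(annotations[, c("cx_mm", "cy_mm", "cz_mm")])
  cl <- singleLinkClusters(centers, distanceThresholdMm)
  lapply(unique(cl), function(g) {
    rows <- which(cl == g)
    ext <- if (kind == "nodule" && !is.null(annotations$ex_mm)) {
      apply(as.matrix(annotations[rows, c("ex_mm", "ey_mm", "ez_mm")]),
            2, max)
    } else rep(NA_real_, 3)
    new("ConsensusObject", kind = kind,
        centerMm = unname(colMeans(centers[rows, , drop = FALSE])),
        approvalCount = length(rows), extentMm = unname(ext),
        sourceScan = scanId)
  })
}

#' Eliminate nodule/non-nodule conflicts
#'
#' Any nodule and non-nodule consensus pair whose centers lie closer than
#' \code{distanceThresholdMm} is ambiguous (the same structure called both
#' ways by different readers); both members of every such pair are removed.
#'
#' @param nodules,nonNodules lists of \linkS4class{ConsensusObject} from
#'   the same scan.
#' @param distanceThresholdMm positive threshold in mm.
#' @return List with elements \code{nodules} and \code{nonNodules} after
#'   removal.
#' @export
eliminateConflicts <- function(nodules, nonNodules, distanceThresholdMm = 5) {
  dropN <- logical(length(nodules))
  dropM <- logical(length(nonNodules))
  for (i in seq_along(nodules)) for (j in seq_along(nonNodules)) {
    d <- sqrt(sum((nodules[[i]]@centerMm - nonNodules[[j]]@centerMm)^2))
    if (d < distanceThresholdMm) { dropN[i] <- TRUE; dropM[j] <- TRUE }
  }
  list(nodules = nodules[!dropN], nonNodules = nonNodules[!dropM])
}

#' Full consensus pipeline for one scan's annotation rows
#'
#' Merges each kind separately, eliminates cross-kind conflicts and
#' filters by the minimum approval count.
#'
#' @param annotations annotation rows of one scan.
#' @param distanceThresholdMm merge/conflict threshold in mm.
#' @param minApproval minimum number of approving readers (default 1).
#' @return List of retained \linkS4class{ConsensusObject}.
#' @export
scanConsensus <- function(annotations, distanceThresholdMm = 5,
                          minApproval = 1L) {
  nod <- mergeReaderAnnotations(
    annotations[annotations$kind == "nodule", , drop = FALSE],
    distanceThresholdMm)
  non <- mergeReaderAnnotations(
    annotations[annotations$kind == "non_nodule", , drop = FALSE],
    distanceThresholdMm)
  kept <- eliminateConflicts(nod, non, distanceThresholdMm)
  out <- c(kept$nodules, kept$nonNodules)
  out[vapply(out, function(o) o@approvalCount >= minApproval, logical(1))]
}

#' Extract a resolution-normalized volume of interest
#'
#' Crops a physical cube (\code{cubeMm} mm a side, i.e. round(cubeMm /
#' spacing) native voxels per axis) around the consensus center, shifts
#' the crop window inside the volume when the center is too close to a
#' border (no zero padding, which would leak label information), resamples
#' it to \code{outRes}^3 voxels by trilinear interpolation, and min-max
#' normalizes the intensities to [0, 1] (a constant region maps to all
#' zeros).
#'
#' @param scan a \linkS4class{SyntheticScan}, or a 3D array (then
#'   \code{spacingMm} must be given).
#' @param consensus the \linkS4class{ConsensusObject} to center on.
#' @param cubeMm physical cube edge in mm (default 30).
#' @param outRes output resolution per axis (default 56).
#' @param spacingMm voxel spacing when \code{scan} is a plain array.
#' @return A \linkS4class{VolumeOfInterest}.
#' @export
extractVoi <- function(scan, consensus, cubeMm = 30, outRes = 56L,
                       spacingMm = NULL) {
  if (is(scan, "SyntheticScan")) {
    volume <- scan@volume; spacingMm <- scan@spacingMm
  } else {
    volume <- scan
    stopifnot(!is.null(spacingMm))
  }
  d <- dim(volume)
  bounds <- d * spacingMm
  ctr <- consensus@centerMm
  if (any(ctr < 0) || any(ctr > bounds))
    stop("geometry error: consensus center outside scan bounds")
  n <- round(cubeMm / spacingMm)
  if (any(n > d))
    stop("geometry error: cube does not fit inside the scan")
  centerVox <- ctr / spacingMm + 0.5
  c0 <- centerVox - (n - 1) / 2
  c0 <- pmin(pmax(c0, 1), d - n + 1)
  ax <- lapply(1:3, function(a)
    c0[a] + (seq_len(outRes) - 1) * (n[a] - 1) / (outRes - 1))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  vals <- trilinearSample(volume, pts)
  cube <- array(vals, dim = rep(outRes, 3))
  rng <- range(cube)
  # treat numerically-constant regions as constant (divide-by-zero guard)
  if (rng[2] - rng[1] > 1e-10 * max(1, abs(rng[2])))
    cube <- (cube - rng[1]) / (rng[2] - rng[1])
  else cube <- array(0, dim = dim(cube))
  new("VolumeOfInterest", voiData = cube, label = consensus@kind,
      consensus = consensus, nativeCubeVoxels = as.integer(n))
}

perspectiveAxis <- c(V1 = 3L, V2 = 2L, V3 = 1L)

extractPlane <- function(cube, axis, k) {
  switch(axis, cube[k, , ], cube[, k, ], cube[, , k])
}

#' Select equally spaced slices of one perspective of a VOI
#'
#' Determines the object's span along the perspective's normal axis (for
#' nodules, from the annotated consensus extent around the cube center;
#' for non-nodules, which carry no boundary annotation, the full plane
#' range) and picks \code{nSlices} plane indices at equal intervals
#' spanning it: \code{round(seq(start, end, length.out = nSlices))}, both
#' endpoints included. A degenerate span with fewer planes than
#' \code{nSlices} repeats boundary planes and raises a warning.
#'
#' @param voi a \linkS4class{VolumeOfInterest}.
#' @param perspective "V1" (transverse XY, planes along z), "V2" (coronal
#'   XZ, planes along y) or "V3" (sagittal YZ, planes along x).
#' @param nSlices number of slices (default 6).
#' @param cubeMm physical cube edge used at extraction (default 30).
#' @return A \linkS4class{PerspectiveStack}.
#' @export
selectSlices <- function(voi, perspective = c("V1", "V2", "V3"),
                         nSlices = 6L, cubeMm = 30) {
  perspective <- match.arg(perspective)
  axis <- perspectiveAxis[[perspective]]
  res <- dim(voi@voiData)[axis]
  ext <- voi@consensus@extentMm[axis]
  if (voi@label == "nodule" && is.finite(ext)) {
    mmPerPlane <- cubeMm / res
    half <- (ext / 2) / mmPerPlane
    mid <- (res + 1) / 2
    start <- max(1L, as.integer(round(mid - half)))
    end <- min(res, as.integer(round(mid + half)))
  } else {
    start <- 1L; end <- res
  }
  if (nSlices == 1L) {
    idx <- as.integer(round((start + end) / 2))
  } else {
    idx <- as.integer(round(seq(start, end, length.out = nSlices)))
  }
  if (anyDuplicated(idx))
    warning("degenerate span (", end - start + 1L, " planes < ", nSlices,
            " slices): boundary planes repeated")
  slices <- lapply(idx, function(k) extractPlane(voi@voiData, axis, k))
  new("PerspectiveStack", perspective = perspective, slices = slices,
      sliceIndices = idx)
}

#' Build the three perspective stacks of a VOI
#'
#' @param voi a \linkS4class{VolumeOfInterest}.
#' @param nSlices slices per perspective (default 6).
#' @param cubeMm physical cube edge in mm.
#' @return Named list of three \linkS4class{PerspectiveStack} (V1, V2, V3).
#' @export
voiToStacks <- function(voi, nSlices = 6L, cubeMm = 30) {
  out <- lapply(PERSPECTIVES, function(p)
    selectSlices(voi, p, nSlices, cubeMm))
  names(out) <- PERSPECTIVES
  out
}

#' Stratified train/test split
#'
#' Splits labeled objects into a training set of exactly
#' \code{floor(trainFrac * n)} objects and the complementary test set,
#' stratified by label with largest-remainder apportionment so each
#' split's class balance stays within one object of the overall balance.
#'
#' @param labels character vector of object labels (or a list of records
#'   each carrying \code{$label}).
#' @param trainFrac training fraction in (0, 1), default 0.7.
#' @param seed integer RNG seed.
#' @return List with integer index vectors \code{train} and \code{test}.
#' @export
splitDataset <- function(labels, trainFrac = 0.7, seed = 1L) {
  stopifnot(trainFrac > 0, trainFrac < 1)
  if (is.list(labels))
    labels <- vapply(labels, function(r) r$label, character(1))
  n <- length(labels)
  set.seed(seed)
  target <- floor(trainFrac * n)
  classes <- sort(unique(labels))
  raw <- vapply(classes, function(cl) trainFrac * sum(labels == cl),
                numeric(1))
  take <- floor(raw)
  rem <- target - sum(take)
  if (rem > 0) {
    ord <- order(raw - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  train <- integer(0)
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    train <- c(train, sample(idx)[seq_len(take[ci])])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}
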