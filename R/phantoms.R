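## Synthetic CT-like phantoms: bright quasi-spherical nodules vs confusable
## distractors (tubes, dim blobs, speckle patches) on a noisy background,
## annotated by several simulated readers with center jitter. The generator
## gives every downstream stage (consensus, VOI extraction, hierarchical
## training, evaluation) a self-contained, seeded data source.

#' Default phantom generator configuration
#'
#' Returns the list of parameters that define the simulated study
#' conditions: a 96x96x96 voxel grid at 0.6 mm isotropic spacing (a 30 mm
#' cube spans 50 native voxels, so VOI extraction exercises the 50 -> 56
#' resampling), additive Gaussian background noise, four simulated readers
#' with 1 mm center jitter and 0.25 miss probability, and the intensity
#' bands of the two separability settings. Under \code{"easy"} the nodule
#' peak is guaranteed to be at least 3x the distractor peak over the same
#' background noise; under \code{"hard"} the two bands overlap.
#'
#' @return Named list of generator parameters (all in mm or intensity
#'   units on the nominal [0, 1] scale).
#' @export
phantomConfig <- function() {
  list(
    dims = c(96L, 96L, 96L),
    spacingMm = c(0.6, 0.6, 0.6),
    backgroundMean = 0.2,
    noiseSd = 0.05,
    peaks = list(
      easy = list(nodule = c(0.6, 0.9), distractor = c(0.1, 0.2)),
      hard = list(nodule = c(0.3, 0.5), distractor = c(0.25, 0.45))
    ),
    noduleDiameterMm = c(8, 24),
    noduleAnisotropy = c(0.85, 1.15),
    tubeWidthMm = 4,
    tubeRatio = 4,
    nReaders = 4L,
    jitterSdMm = 1.0,
    jitterBoundMm = 2.5,
    missProb = 0.25,
    marginMm = 8,
    minSeparationMm = 12
  )
}

## physical center position (mm) of 1-based voxel index i: (i - 0.5) * spacing
voxelCentersMm <- function(n, spacing) (seq_len(n) - 0.5) * spacing

#' Inject an anisotropic Gaussian-profile nodule into a volume
#'
#' Additively blends a blob whose intensity at \code{centerMm} equals
#' \code{peak} and decays with ellipsoidal radius (per-axis Gaussian sigma
#' = extent/4, so the blob has effectively vanished at the extent
#' boundary). The blend is computed only inside the box of full size
#' \code{2 * extentMm} around the center; voxels outside it are untouched.
#'
#' @param volume 3D numeric array, indexed \code{[x, y, z]}.
#' @param spacingMm numeric(3) voxel size in mm.
#' @param centerMm numeric(3) blob center in mm (must lie inside the volume).
#' @param extentMm numeric(3) axis-aligned size in mm (all > 0).
#' @param peak scalar peak intensity added at the center.
#' @return A copy of \code{volume} with the blob added.
#' @export
injectNodule <- function(volume, spacingMm, centerMm, extentMm, peak) {
  stopifnot(length(dim(volume)) == 3L, length(centerMm) == 3L,
            length(extentMm) == 3L, all(extentMm > 0))
  bounds <- dim(volume) * spacingMm
  if (any(centerMm < 0) || any(centerMm > bounds))
    stop("geometry error: center_mm lies outside the volume")
  if (peak == 0) return(volume)
  sig <- extentMm / 4
  idx <- lapply(1:3, function(a) {
    pos <- voxelCentersMm(dim(volume)[a], spacingMm[a])
    which(abs(pos - centerMm[a]) <= extentMm[a])
  })
  if (any(lengths(idx) == 0L)) return(volume)
  dx <- voxelCentersMm(dim(volume)[1], spacingMm[1])[idx[[1]]] - centerMm[1]
  dy <- voxelCentersMm(dim(volume)[2], spacingMm[2])[idx[[2]]] - centerMm[2]
  dz <- voxelCentersMm(dim(volume)[3], spacingMm[3])[idx[[3]]] - centerMm[3]
  q <- outer(outer(dx^2 / sig[1]^2, dy^2 / sig[2]^2, "+"), dz^2 / sig[3]^2, "+")
  volume[idx[[1]], idx[[2]], idx[[3]]] <-
    volume[idx[[1]], idx[[2]], idx[[3]]] + peak * exp(-0.5 * q)
  volume
}

#' Inject a non-nodule distractor structure
#'
#' Three distractor kinds emulate confusable non-nodule structures:
#' \describe{
#'   \item{tube}{an elongated structure (vessel-like): Gaussian cross
#'     section of width \code{widthMm} along a random direction, length
#'     \code{ratio * widthMm}, so its longest/shortest principal extent
#'     ratio is at least ~3 for the default ratio 4.}
#'   \item{blob}{a dim, mildly elongated Gaussian blob.}
#'   \item{speckle}{a patch of additive Gaussian speckle noise (sd =
#'     \code{amplitude}) confined to an ellipsoid around the center.}
#' }
#' Deterministic given \code{seed}.
#'
#' @param volume,spacingMm as in \code{\link{injectNodule}}.
#' @param kind one of "tube", "blob", "speckle".
#' @param params list: \code{centerMm}, \code{peak} (tube/blob) or
#'   \code{amplitude} (speckle), optional \code{widthMm}, \code{ratio},
#'   \code{extentMm}.
#' @param seed integer RNG seed (NULL = use current RNG state).
#' @return A copy of \code{volume} with the distractor added, with the
#'   attribute \code{"extentMm"} giving the bounding extent used.
#' @export
injectDistractor <- function(volume, spacingMm, kind, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centerMm <- params$centerMm
  bounds <- dim(volume) * spacingMm
  if (any(centerMm < 0) || any(centerMm > bounds))
    stop("geometry error: center_mm lies outside the volume")
  out <- switch(kind,
    tube = {
      w <- if (is.null(params$widthMm)) 4 else params$widthMm
      ratio <- if (is.null(params$ratio)) 4 else params$ratio
      stopifnot(w > 0, ratio >= 1)
      L <- ratio * w
      sw <- w / 4
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      half <- L / 2 + 2 * sw
      idx <- lapply(1:3, function(a) {
        pos <- voxelCentersMm(dim(volume)[a], spacingMm[a])
        which(abs(pos - centerMm[a]) <= half)
      })
      px <- voxelCentersMm(dim(volume)[1], spacingMm[1])[idx[[1]]] - centerMm[1]
      py <- voxelCentersMm(dim(volume)[2], spacingMm[2])[idx[[2]]] - centerMm[2]
      pz <- voxelCentersMm(dim(volume)[3], spacingMm[3])[idx[[3]]] - centerMm[3]
      g <- expand.grid(x = px, y = py, z = pz)
      along <- g$x * u[1] + g$y * u[2] + g$z * u[3]
      perp2 <- g$x^2 + g$y^2 + g$z^2 - along^2
      cap <- pmax(0, abs(along) - L / 2)
      add <- params$peak * exp(-perp2 / (2 * sw^2)) * exp(-cap^2 / (2 * sw^2))
      volume[idx[[1]], idx[[2]], idx[[3]]] <-
        volume[idx[[1]], idx[[2]], idx[[3]]] +
        array(add, dim = lengths(idx))
      attr(volume, "extentMm") <- rep(min(L, 30), 3)
      volume
    },
    blob = {
      ext <- if (is.null(params$extentMm))
        runif(1, 8, 20) * runif(3, 0.7, 1.4) else params$extentMm
      ext <- pmin(pmax(ext, 2), 30)
      v <- injectNodule(volume, spacingMm, centerMm, ext, params$peak)
      attr(v, "extentMm") <- ext
      v
    },
    speckle = {
      amp <- params$amplitude
      stopifnot(amp >= 0)
      ext <- if (is.null(params$extentMm)) rep(runif(1, 8, 16), 3) else params$extentMm
      attr(volume, "extentMm") <- ext
      if (amp == 0) return(volume)
      idx <- lapply(1:3, function(a) {
        pos <- voxelCentersMm(dim(volume)[a], spacingMm[a])
        which(abs(pos - centerMm[a]) <= ext[a] / 2)
      })
      dx <- voxelCentersMm(dim(volume)[1], spacingMm[1])[idx[[1]]] - centerMm[1]
      dy <- voxelCentersMm(dim(volume)[2], spacingMm[2])[idx[[2]]] - centerMm[2]
      dz <- voxelCentersMm(dim(volume)[3], spacingMm[3])[idx[[3]]] - centerMm[3]
      r2 <- outer(outer((2 * dx / ext[1])^2, (2 * dy / ext[2])^2, "+"),
                  (2 * dz / ext[3])^2, "+")
      mask <- r2 <= 1
      noise <- array(0, dim = dim(mask))
      noise[mask] <- rnorm(sum(mask), 0, amp)
      volume[idx[[1]], idx[[2]], idx[[3]]] <-
        volume[idx[[1]], idx[[2]], idx[[3]]] + noise
      attr(volume, "extentMm") <- ext
      volume
    },
    stop("configuration error: unknown distractor kind '", kind, "'")
  )
  out
}

#' Simulate multi-reader annotations of one object
#'
#' Each of \code{nReaders} readers independently misses the object with
#' probability \code{missProb}; each retained reader annotates the true
#' center plus isotropic Gaussian jitter (sd \code{jitterSdMm} per axis),
#' truncated so the jitter magnitude never exceeds \code{jitterBoundMm}
#' (redrawn otherwise) — annotations of one object therefore stay within
#' \code{2 * jitterBoundMm} of each other, which keeps them below any
#' consensus threshold chosen above that figure.
#' If every reader misses, the retention vector is redrawn until at least
#' one annotation remains; the returned annotation table carries the
#' attribute \code{"resampled"} recording whether that happened and
#' \code{"initialRetained"}, the first-draw retention count before the
#' at-least-one guard (its mean over seeds is the plain Binomial mean).
#' Nodule
#' readers also annotate a boundary extent (the true extent with small
#' jitter); non-nodules carry only a center, so their extent columns are NA.
#'
#' @param object a \linkS4class{GroundTruthObject}.
#' @param nReaders integer >= 1.
#' @param jitterSdMm non-negative jitter standard deviation in mm.
#' @param missProb miss probability in [0, 1).
#' @param jitterBoundMm maximum jitter magnitude in mm (default 2.5).
#' @param seed integer RNG seed (NULL = use current RNG state).
#' @return The object with its \code{readerAnnotations} slot filled.
#' @export
simulateReaders <- function(object, nReaders = 4L, jitterSdMm = 1.0,
                            missProb = 0.25, jitterBoundMm = 2.5,
                            seed = NULL) {
  stopifnot(nReaders >= 1L, missProb >= 0, missProb < 1, jitterSdMm >= 0,
            jitterBoundMm > 0)
  if (!is.null(seed)) set.seed(seed)
  resampled <- FALSE
  initialRetained <- NA_integer_
  repeat {
    kept <- rbinom(nReaders, 1L, 1 - missProb) == 1L
    if (is.na(initialRetained)) initialRetained <- sum(kept)
    if (any(kept)) break
    resampled <- TRUE
  }
  readers <- which(kept)
  n <- length(readers)
  jitterOne <- function() {
    repeat {
      j <- rnorm(3, 0, jitterSdMm)
      if (sqrt(sum(j^2)) <= jitterBoundMm) return(j)
    }
  }
  centers <- matrix(object@centerMm, n, 3, byrow = TRUE) +
    if (jitterSdMm > 0) t(vapply(seq_len(n), function(i) jitterOne(),
                                 numeric(3))) else 0
  if (object@kind == "nodule") {
    ext <- matrix(object@extentMm, n, 3, byrow = TRUE) *
      matrix(runif(3 * n, 0.9, 1.1), n, 3)
    ext <- pmin(pmax(ext, 0.5), 30)
  } else {
    ext <- matrix(NA_real_, n, 3)
  }
  ann <- data.frame(
    reader_id = readers, kind = object@kind,
    cx_mm = centers[, 1], cy_mm = centers[, 2], cz_mm = centers[, 3],
    ex_mm = ext[, 1], ey_mm = ext[, 2], ez_mm = ext[, 3]
  )
  attr(ann, "resampled") <- resampled
  attr(ann, "initialRetained") <- initialRetained
  initialize(object, readerAnnotations = ann)
}

## place nObjects centers in the scan interior on a jittered 2x2x2 cell grid
## so that pairwise separation stays >= minSeparationMm
placeCenters <- function(nObjects, boundsMm, marginMm, minSepMm) {
  lo <- rep(marginMm, 3); hi <- boundsMm - marginMm
  cellW <- (hi - lo) / 2
  cells <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  if (nObjects > nrow(cells))
    stop("at most ", nrow(cells), " objects per scan are supported")
  pick <- sample(nrow(cells), nObjects)
  jitterMax <- pmax(cellW / 2 - minSepMm / 2, 0)
  t(vapply(pick, function(i) {
    ctr <- lo + (cells[i, ] + 0.5) * cellW
    ctr + runif(3, -1, 1) * jitterMax
  }, numeric(3)))
}

generateScan <- function(scanId, nNodule, nDistractor, separability, config,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- config$dims
  sp <- config$spacingMm
  vol <- array(rnorm(prod(dims), config$backgroundMean, config$noiseSd),
               dim = dims)
  bands <- config$peaks[[separability]]
  nObj <- nNodule + nDistractor
  centers <- placeCenters(nObj, dims * sp, config$marginMm,
                          config$minSeparationMm)
  kinds <- sample(c(rep("nodule", nNodule), rep("non_nodule", nDistractor)))
  distractorKinds <- c("tube", "blob", "speckle")
  di <- 0L
  objects <- vector("list", nObj)
  for (i in seq_len(nObj)) {
    ctr <- centers[i, ]
    if (kinds[i] == "nodule") {
      d <- runif(1, config$noduleDiameterMm[1], config$noduleDiameterMm[2])
      ext <- pmin(pmax(d * runif(3, config$noduleAnisotropy[1],
                                 config$noduleAnisotropy[2]), 2), 30)
      peak <- runif(1, bands$nodule[1], bands$nodule[2])
      vol <- injectNodule(vol, sp, ctr, ext, peak)
      obj <- new("GroundTruthObject", kind = "nodule", centerMm = ctr,
                 extentMm = ext, peakIntensity = peak,
                 readerAnnotations = data.frame())
    } else {
      di <- di + 1L
      dk <- distractorKinds[(di - 1L) %% 3L + 1L]
      peak <- runif(1, bands$distractor[1], bands$distractor[2])
      params <- list(centerMm = ctr, peak = peak, amplitude = peak / 2,
                     widthMm = config$tubeWidthMm, ratio = config$tubeRatio)
      vol <- injectDistractor(vol, sp, dk, params)
      ext <- attr(vol, "extentMm")
      attr(vol, "extentMm") <- NULL
      obj <- new("GroundTruthObject", kind = "non_nodule", centerMm = ctr,
                 extentMm = pmin(pmax(ext, 2), 30), peakIntensity = peak,
                 readerAnnotations = data.frame())
    }
    objects[[i]] <- simulateReaders(obj, config$nReaders, config$jitterSdMm,
                                    config$missProb, config$jitterBoundMm)
  }
  new("SyntheticScan", scanId = scanId, volume = vol, spacingMm = sp,
      objects = objects)
}

#' Generate a synthetic annotated dataset
#'
#' Generates \code{nScans} phantom scans with \code{objectsPerScan} objects
#' each, class-balanced to within one object overall, each object annotated
#' by the configured simulated readers. Centers are placed at least
#' \code{minSeparationMm} apart so consensus clustering merges only
#' same-object annotations.
#'
#' @param nScans integer >= 1.
#' @param objectsPerScan integer 1..8.
#' @param separability "easy" (nodule peak >= 3x distractor peak over the
#'   same background noise) or "hard" (overlapping intensity bands).
#' @param config generator configuration, see \code{\link{phantomConfig}}.
#' @param seed integer RNG seed.
#' @return List with \code{scans} (list of \linkS4class{SyntheticScan}) and
#'   \code{annotations}, a data.frame with one row per reader annotation and
#'   columns \code{scan_id, reader_id, kind, cx_mm, cy_mm, cz_mm, ex_mm,
#'   ey_mm, ez_mm}.
#' @export
generateDataset <- function(nScans, objectsPerScan = 4L,
                            separability = c("easy", "hard"),
                            config = phantomConfig(), seed = 1L) {
  separability <- match.arg(separability)
  stopifnot(nScans >= 1L, objectsPerScan >= 1L)
  set.seed(seed)
  base <- objectsPerScan %/% 2L
  extra <- objectsPerScan %% 2L
  scans <- vector("list", nScans)
  for (s in seq_len(nScans)) {
    nNod <- base + if (extra == 1L && s %% 2L == 1L) 1L else 0L
    scans[[s]] <- generateScan(sprintf("scan%04d", s), nNod,
                               objectsPerScan - nNod, separability, config)
  }
  ann <- do.call(rbind, lapply(scans, function(sc) {
    do.call(rbind, lapply(sc@objects, function(ob) {
      cbind(scan_id = sc@scanId, ob@readerAnnotations)
    }))
  }))
  rownames(ann) <- NULL
  list(scans = scans, annotations = ann)
}

#' Trilinear sample of a volume at a physical position
#'
#' @param volume 3D array; \code{spacingMm} numeric(3); \code{posMm}
#'   numeric(3) position in mm.
#' @param spacingMm voxel spacing in mm.
#' @param posMm physical position in mm.
#' @return Interpolated scalar intensity.
#' @export
sampleVolumeMm <- function(volume, spacingMm, posMm) {
  trilinearSample(volume, matrix(posMm / spacingMm - 0.5, 1, 3) + 1)
}

#' Accuracy of the best intensity threshold on object central intensities
#'
#' The brute-force oracle behind the separability dial: samples each
#' ground-truth object's central intensity from its scan, sweeps all
#' candidate thresholds and returns the best nodule-vs-non-nodule accuracy.
#'
#' @param scans list of \linkS4class{SyntheticScan}.
#' @return Best achievable accuracy in [0, 1].
#' @export
intensityThresholdAccuracy <- function(scans) {
  vals <- list(); labs <- list()
  for (sc in scans) {
    for (ob in sc@objects) {
      vals <- c(vals, sampleVolumeMm(sc@volume, sc@spacingMm, ob@centerMm))
      labs <- c(labs, ob@kind == "nodule")
    }
  }
  v <- unlist(vals); y <- unlist(labs)
  cand <- c(-Inf, sort(unique(v)), Inf)
  best <- 0
  for (t in cand) {
    acc <- mean((v > t) == y)
    best <- max(best, acc, 1 - acc)
  }
  best
}
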