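#' @import methods
#' @importFrom nnet nnet
#' @importFrom stats rnorm runif rbinom predict quantile sd
#' @importFrom utils head tail
#' @useDynLib hierfusion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

KIND_LEVELS <- c("nodule", "non_nodule")
PERSPECTIVES <- c("V1", "V2", "V3")

#' SyntheticScan: one phantom CT-like volume with its ground-truth objects
#'
#' A 3D scalar intensity grid with physical voxel spacing and the list of
#' objects (nodules and distractors) injected into it, each carrying its
#' simulated multi-reader annotations.
#'
#' @slot scanId character scan identifier.
#' @slot volume 3D numeric array of intensities, indexed \code{[x, y, z]}.
#' @slot spacingMm numeric(3), physical voxel size per axis in mm (all > 0).
#' @slot objects list of \linkS4class{GroundTruthObject}.
#' @export
setClass("SyntheticScan",
  representation(scanId = "character", volume = "array",
                 spacingMm = "numeric", objects = "list"))

setValidity("SyntheticScan", function(object) {
  msg <- character()
  if (length(dim(object@volume)) != 3L)
    msg <- c(msg, "volume must be a 3D array")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    msg <- c(msg, "spacingMm must be 3 positive values")
  bounds <- dim(object@volume) * object@spacingMm
  for (ob in object@objects) {
    if (!is(ob, "GroundTruthObject"))
      msg <- c(msg, "objects must all be GroundTruthObject")
    else if (any(ob@centerMm < 0) || any(ob@centerMm > bounds))
      msg <- c(msg, "object center outside the scan's physical bounds")
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruthObject: one injected object and its reader annotations
#'
#' @slot kind "nodule" or "non_nodule".
#' @slot centerMm numeric(3) true center in mm.
#' @slot extentMm numeric(3) axis-aligned size in mm, each in (0, 30].
#' @slot peakIntensity scalar peak intensity above background.
#' @slot readerAnnotations data.frame with columns
#'   \code{reader_id, kind, cx_mm, cy_mm, cz_mm, ex_mm, ey_mm, ez_mm}.
#' @export
setClass("GroundTruthObject",
  representation(kind = "character", centerMm = "numeric",
                 extentMm = "numeric", peakIntensity = "numeric",
                 readerAnnotations = "data.frame"))

setValidity("GroundTruthObject", function(object) {
  msg <- character()
  if (!object@kind %in% KIND_LEVELS) msg <- c(msg, "kind must be nodule/non_nodule")
  if (length(object@centerMm) != 3L) msg <- c(msg, "centerMm must be length 3")
  if (length(object@extentMm) != 3L || any(object@extentMm <= 0) ||
      any(object@extentMm > 30))
    msg <- c(msg, "extentMm components must lie in (0, 30]")
  if (length(msg)) msg else TRUE
})

#' ConsensusObject: merged multi-reader annotation
#'
#' The result of single-linkage clustering of same-kind reader annotations:
#' the arithmetic-mean center, the number of approving readers and (for
#' nodules) the element-wise maximum annotated extent.
#'
#' @slot kind "nodule" or "non_nodule".
#' @slot centerMm numeric(3) averaged center in mm.
#' @slot approvalCount integer number of merged annotations (>= 1).
#' @slot extentMm numeric(3) element-wise max of merged extents (NA for
#'   non-nodules, which carry no boundary annotation).
#' @slot sourceScan character scan id.
#' @export
setClass("ConsensusObject",
  representation(kind = "character", centerMm = "numeric",
                 approvalCount = "integer", extentMm = "numeric",
                 sourceScan = "character"))

setValidity("ConsensusObject", function(object) {
  msg <- character()
  if (!object@kind %in% KIND_LEVELS) msg <- c(msg, "bad kind")
  if (object@approvalCount < 1L) msg <- c(msg, "approvalCount must be >= 1")
  if (length(object@centerMm) != 3L) msg <- c(msg, "centerMm must be length 3")
  if (length(msg)) msg else TRUE
})

#' VolumeOfInterest: normalized intensity cube around a consensus center
#'
#' A physical cube (default 30 mm a side) cropped around a consensus center,
#' resampled to a fixed voxel resolution (default 56^3) by trilinear
#' interpolation and min-max normalized to [0, 1].
#'
#' @slot voiData 3D numeric array, out_res^3, values in [0, 1].
#' @slot label "nodule" or "non_nodule".
#' @slot consensus the \linkS4class{ConsensusObject} it was extracted around.
#' @slot nativeCubeVoxels integer(3): native crop size before resampling.
#' @export
setClass("VolumeOfInterest",
  representation(voiData = "array", label = "character",
                 consensus = "ConsensusObject", nativeCubeVoxels = "integer"))

setValidity("VolumeOfInterest", function(object) {
  msg <- character()
  d <- dim(object@voiData)
  if (length(d) != 3L || length(unique(d)) != 1L)
    msg <- c(msg, "voiData must be a cubic 3D array")
  rng <- range(object@voiData)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    msg <- c(msg, "voiData values must lie in [0, 1]")
  if (!object@label %in% KIND_LEVELS) msg <- c(msg, "bad label")
  if (length(msg)) msg else TRUE
})

#' PerspectiveStack: the selected slices of one perspective of one VOI
#'
#' @slot perspective "V1" (transverse XY), "V2" (coronal XZ) or
#'   "V3" (sagittal YZ).
#' @slot slices list of 2D matrices, one per selected plane, in plane order.
#' @slot sliceIndices integer source plane indices (1-based, non-decreasing;
#'   strictly increasing unless the object span was degenerate).
#' @export
setClass("PerspectiveStack",
  representation(perspective = "character", slices = "list",
                 sliceIndices = "integer"))

setValidity("PerspectiveStack", function(object) {
  msg <- character()
  if (!object@perspective %in% PERSPECTIVES)
    msg <- c(msg, "perspective must be one of V1/V2/V3")
  if (length(object@slices) != length(object@sliceIndices))
    msg <- c(msg, "slices and sliceIndices lengths differ")
  if (is.unsorted(object@sliceIndices))
    msg <- c(msg, "sliceIndices must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' FilterSpec: parameters of one feature-image filter
#'
#' Houses the parameters of the four feature-image families: the LoG shape
#' parameter \code{sigma}; the Gabor envelope widths \code{sigmaX},
#' \code{sigmaY} and center frequencies \code{omegaX0}, \code{omegaY0}
#' (cycles/pixel); the bilateral/trilateral window size \code{windowN}
#' (odd), spatial width \code{sigmaS}, intensity-range width \code{sigmaR}
#' and Laplacian-range width \code{sigmaL}; and the scale factor \code{k}
#' of the difference-of-trilateral operator.
#'
#' @slot family one of "log", "gabor", "bilateral", "trilateral",
#'   "diff_trilateral".
#' @slot sigma,sigmaX,sigmaY,omegaX0,omegaY0,sigmaS,sigmaR,sigmaL,k numeric
#'   filter parameters; only the family-relevant ones are used.
#' @slot windowN odd integer neighborhood size (>= 3).
#' @slot gaborOutput "real" or "magnitude" response for the Gabor family.
#' @export
setClass("FilterSpec",
  representation(family = "character", sigma = "numeric",
                 sigmaX = "numeric", sigmaY = "numeric",
                 omegaX0 = "numeric", omegaY0 = "numeric",
                 windowN = "integer", sigmaS = "numeric",
                 sigmaR = "numeric", sigmaL = "numeric", k = "numeric",
                 gaborOutput = "character"))

setValidity("FilterSpec", function(object) {
  msg <- character()
  fam <- object@family
  if (!fam %in% c("log", "gabor", "bilateral", "trilateral", "diff_trilateral"))
    msg <- c(msg, "unknown filter family")
  pos <- function(x) length(x) == 1L && is.finite(x) && x > 0
  if (fam == "log" && !pos(object@sigma)) msg <- c(msg, "log: sigma must be > 0")
  if (fam == "gabor" && !(pos(object@sigmaX) && pos(object@sigmaY)))
    msg <- c(msg, "gabor: sigmaX and sigmaY must be > 0")
  if (fam %in% c("bilateral", "trilateral", "diff_trilateral")) {
    if (object@windowN < 3L || object@windowN %% 2L == 0L)
      msg <- c(msg, "windowN must be odd and >= 3")
    if (!(pos(object@sigmaS) && pos(object@sigmaR)))
      msg <- c(msg, "sigmaS and sigmaR must be > 0")
  }
  if (fam %in% c("trilateral", "diff_trilateral") && !pos(object@sigmaL))
    msg <- c(msg, "sigmaL must be > 0")
  if (fam == "diff_trilateral" && !(length(object@k) == 1L && object@k > 1))
    msg <- c(msg, "k must be > 1")
  if (length(msg)) msg else TRUE
})

#' FeatureImage: a filtered slice
#'
#' @slot featureData 2D numeric matrix, same shape as the source slice.
#' @slot spec the \linkS4class{FilterSpec} that produced it.
#' @slot sourceId character identifier of the source slice.
#' @export
setClass("FeatureImage",
  representation(featureData = "matrix", spec = "FilterSpec",
                 sourceId = "character"))

setValidity("FeatureImage", function(object) {
  if (!all(is.finite(object@featureData))) "featureData must be finite" else TRUE
})

#' SliceCnn: the compact convolutional slice module
#'
#' Four conv(3x3, same) + ReLU + 2x2 max-pool blocks with 8/16/32/64
#' filters, a 32-unit fully connected ReLU layer and a 2-class softmax
#' head, trained with Adam on the cross-entropy loss.
#'
#' @slot weights list of parameter arrays (conv kernels, biases, FC weights).
#' @slot config list of architecture/training hyperparameters.
#' @slot trained logical.
#' @slot trainingLog data.frame with epoch, train_loss, val_loss, val_acc.
#' @export
setClass("SliceCnn",
  representation(weights = "list", config = "list", trained = "logical",
                 trainingLog = "data.frame"))

#' VolumeScorer: anything that can score a VOI's nodule probability
#'
#' Virtual parent for objects usable as members of the multi-feature
#' top-level fusion: given a record with the three perspective stacks (and
#' label metadata), produce a nodule probability in [0, 1].
#' @export
setClass("VolumeScorer", representation("VIRTUAL"))

#' CallbackScorer: a VolumeScorer wrapping a plain function
#'
#' @slot fn function(record) -> numeric nodule score in [0, 1].
#' @export
setClass("CallbackScorer", contains = "VolumeScorer",
  representation(fn = "function"))

#' HierarchicalModel: the trained slice/perspective/volume triple
#'
#' The complete multi-perspective hierarchy: three slice CNNs (one per
#' perspective), three perspective fusion modules, the volume fusion
#' module, an optional feature-image front end, and provenance.
#'
#' @slot sliceModules named list of three \linkS4class{SliceCnn} (V1..V3).
#' @slot perspectiveModules named list of three fitted perspective fusers.
#' @slot volumeModule fitted volume fuser.
#' @slot featureSpec a \linkS4class{FilterSpec} or NULL (raw-image model).
#' @slot provenance list (configs, seeds, training logs).
#' @export
setClass("HierarchicalModel", contains = "VolumeScorer",
  representation(sliceModules = "list", perspectiveModules = "list",
                 volumeModule = "ANY", featureSpec = "ANY",
                 provenance = "list"))

setValidity("HierarchicalModel", function(object) {
  msg <- character()
  if (!identical(sort(names(object@sliceModules)), sort(PERSPECTIVES)))
    msg <- c(msg, "sliceModules must be named V1, V2, V3")
  if (!identical(sort(names(object@perspectiveModules)), sort(PERSPECTIVES)))
    msg <- c(msg, "perspectiveModules must be named V1, V2, V3")
  if (!is.null(object@featureSpec) && !is(object@featureSpec, "FilterSpec"))
    msg <- c(msg, "featureSpec must be NULL or a FilterSpec")
  if (length(msg)) msg else TRUE
})

#' MfmpfModel: multi-feature top-level fusion over several hierarchies
#'
#' @slot members list of \linkS4class{VolumeScorer} (typically the four
#'   feature-image hierarchies plus the raw-image one).
#' @slot topModule fitted top fusion classifier over member volume scores.
#' @slot provenance list.
#' @export
setClass("MfmpfModel",
  representation(members = "list", topModule = "ANY", provenance = "list"))

setValidity("MfmpfModel", function(object) {
  ok <- all(vapply(object@members, function(m) is(m, "VolumeScorer"), logical(1)))
  if (!ok) "members must all be VolumeScorer objects" else TRUE
})

#' EvaluationReport: level-wise metric table with ROC curves
#'
#' @slot metrics data.frame with columns
#'   \code{level, perspective, acc, auc, f1, sens, spec}.
#' @slot roc named list of ROC point data.frames (fpr, tpr, threshold).
#' @slot fpPerScan numeric: volume-level false positives per distinct scan.
#' @slot nScans,nObjects integer counts of the evaluated set.
#' @export
setClass("EvaluationReport",
  representation(metrics = "data.frame", roc = "list",
                 fpPerScan = "numeric", nScans = "integer",
                 nObjects = "integer"))

## ---- show methods -------------------------------------------------------

setMethod("show", "SyntheticScan", function(object) {
  cat("SyntheticScan", object@scanId, ":",
      paste(dim(object@volume), collapse = " x "), "voxels @",
      paste(signif(object@spacingMm, 3), collapse = "/"), "mm,",
      length(object@objects), "objects\n")
})

setMethod("show", "VolumeOfInterest", function(object) {
  cat("VolumeOfInterest (", object@label, "): ",
      paste(dim(object@voiData), collapse = " x "),
      ", native crop ", paste(object@nativeCubeVoxels, collapse = " x "),
      ", approval ", object@consensus@approvalCount, "\n", sep = "")
})

setMethod("show", "PerspectiveStack", function(object) {
  cat("PerspectiveStack", object@perspective, "with",
      length(object@slices), "slices at planes",
      paste(object@sliceIndices, collapse = ", "), "\n")
})

setMethod("show", "FilterSpec", function(object) {
  cat("FilterSpec:", object@family, "\n")
})

setMethod("show", "SliceCnn", function(object) {
  cat("SliceCnn (", if (object@trained) "trained" else "untrained", "): ",
      paste(object@config$convFilters, collapse = "-"),
      " conv filters, fc ", object@config$fcUnits, "\n", sep = "")
})

setMethod("show", "HierarchicalModel", function(object) {
  cat("HierarchicalModel (",
      if (is.null(object@featureSpec)) "raw images"
      else paste0("feature: ", object@featureSpec@family),
      "): 3 slice modules, 3 perspective modules, 1 volume module\n",
      sep = "")
})

setMethod("show", "MfmpfModel", function(object) {
  cat("MfmpfModel:", length(object@members), "members + top fusion module\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport over", object@nObjects, "objects /",
      object@nScans, "scans; fp/scan =", signif(object@fpPerScan, 4), "\n")
  print(object@metrics, digits = 3)
})

## ---- accessors ----------------------------------------------------------

#' Accessors for the core classes
#'
#' @param object an object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("scanVolume", function(object) standardGeneric("scanVolume"))
#' @rdname accessors
#' @export
setMethod("scanVolume", "SyntheticScan", function(object) object@volume)

#' @rdname accessors
#' @export
setGeneric("spacingMm", function(object) standardGeneric("spacingMm"))
#' @rdname accessors
#' @export
setMethod("spacingMm", "SyntheticScan", function(object) object@spacingMm)

#' @rdname accessors
#' @export
setGeneric("scanObjects", function(object) standardGeneric("scanObjects"))
#' @rdname accessors
#' @export
setMethod("scanObjects", "SyntheticScan", function(object) object@objects)

#' @rdname accessors
#' @export
setGeneric("voiData", function(object) standardGeneric("voiData"))
#' @rdname accessors
#' @export
setMethod("voiData", "VolumeOfInterest", function(object) object@voiData)

#' @rdname accessors
#' @export
setGeneric("voiLabel", function(object) standardGeneric("voiLabel"))
#' @rdname accessors
#' @export
setMethod("voiLabel", "VolumeOfInterest", function(object) object@label)

#' @rdname accessors
#' @export
setGeneric("stackSlices", function(object) standardGeneric("stackSlices"))
#' @rdname accessors
#' @export
setMethod("stackSlices", "PerspectiveStack", function(object) object@slices)

#' @rdname accessors
#' @export
setGeneric("sliceIndices", function(object) standardGeneric("sliceIndices"))
#' @rdname accessors
#' @export
setMethod("sliceIndices", "PerspectiveStack", function(object) object@sliceIndices)

#' @rdname accessors
#' @export
setGeneric("featureData", function(object) standardGeneric("featureData"))
#' @rdname accessors
#' @export
setMethod("featureData", "FeatureImage", function(object) object@featureData)

#' @rdname accessors
#' @export
setGeneric("filterFamily", function(object) standardGeneric("filterFamily"))
#' @rdname accessors
#' @export
setMethod("filterFamily", "FilterSpec", function(object) object@family)

#' @rdname accessors
#' @export
setGeneric("sliceModules", function(object) standardGeneric("sliceModules"))
#' @rdname accessors
#' @export
setMethod("sliceModules", "HierarchicalModel", function(object) object@sliceModules)

#' @rdname accessors
#' @export
setGeneric("perspectiveModules", function(object) standardGeneric("perspectiveModules"))
#' @rdname accessors
#' @export
setMethod("perspectiveModules", "HierarchicalModel",
          function(object) object@perspectiveModules)

#' @rdname accessors
#' @export
setGeneric("volumeModule", function(object) standardGeneric("volumeModule"))
#' @rdname accessors
#' @export
setMethod("volumeModule", "HierarchicalModel", function(object) object@volumeModule)

#' @rdname accessors
#' @export
setGeneric("featureSpec", function(object) standardGeneric("featureSpec"))
#' @rdname accessors
#' @export
setMethod("featureSpec", "HierarchicalModel", function(object) object@featureSpec)

#' @rdname accessors
#' @export
setGeneric("reportMetrics", function(object) standardGeneric("reportMetrics"))
#' @rdname accessors
#' @export
setMethod("reportMetrics", "EvaluationReport", function(object) object@metrics)

#' @rdname accessors
#' @export
setGeneric("fpPerScanRate", function(object) standardGeneric("fpPerScanRate"))
#' @rdname accessors
#' @export
setMethod("fpPerScanRate", "EvaluationReport", function(object) object@fpPerScan)
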