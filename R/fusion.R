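## The hierarchical deep-fusion core: score re-arrangement, perspective
## modules, the volume module, the modular training protocol (train each
## level separately on the frozen previous level's outputs), and the
## multi-feature top fusion level.

#' Fusion-level configuration
#'
#' The perspective, volume and top fusion modules are single-hidden-layer
#' feedforward classifiers (fitted with \pkg{nnet}); \code{hidden} sets
#' the hidden width, \code{maxit} the optimizer iteration cap,
#' \code{restarts} the number of seeded restarts from which the best
#' training fit is kept, and \code{decay} the L2 weight decay — a small
#' nonzero decay keeps the output probabilities graded on separable
#' inputs instead of saturating at exactly 0/1, so downstream ROC sweeps
#' remain informative.
#'
#' @param nSlices slices per perspective stack (default 6).
#' @param hidden hidden units of the fusion classifiers (default 8).
#' @param maxit optimizer iterations per restart (default 200).
#' @param restarts seeded restarts (default 3).
#' @param decay L2 weight decay of the fusion classifiers (default 1e-3).
#' @param dcnn slice-module configuration, see \code{\link{dcnnConfig}}.
#' @return Named configuration list.
#' @export
mpfConfig <- function(nSlices = 6L, hidden = 8L, maxit = 200L,
                      restarts = 3L, decay = 1e-3, dcnn = dcnnConfig()) {
  list(nSlices = as.integer(nSlices), hidden = as.integer(hidden),
       maxit = as.integer(maxit), restarts = as.integer(restarts),
       decay = decay, dcnn = dcnn)
}

## ---- single-hidden-layer fusion classifier over score vectors ----------

trainScoreFusion <- function(x, labels, hidden = 8L, maxit = 200L,
                             restarts = 3L, seed = 1L, decay = 1e-3) {
  x <- as.matrix(x)
  y <- labelsToInt(labels)
  if (nrow(x) != length(y)) stop("feature/label length mismatch")
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + (r - 1L) * 1000L)
    fit <- nnet::nnet(x, y, size = hidden, entropy = TRUE, maxit = maxit,
                      decay = decay, trace = FALSE)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  structure(list(fit = best, hidden = hidden, inputLength = ncol(x)),
            class = "fusionMlp")
}

predictScoreFusion <- function(module, x) {
  x <- as.matrix(x)
  if (ncol(x) != module$inputLength)
    stop("input length ", ncol(x), " does not match the module's expected ",
         module$inputLength)
  p <- as.numeric(predict(module$fit, x))
  pmin(pmax(p, 0), 1)
}

## ---- score re-arrangement ----------------------------------------------

#' Re-arrange slice scores into the perspective-module feature vector
#'
#' Extracts the nodule-class probability of every slice, in slice order,
#' forming the input feature vector of the perspective module (length =
#' number of slices).
#'
#' @param scores slice score matrix from \code{\link{predictSliceScores}}
#'   (one row per slice, columns non_nodule/nodule).
#' @return Numeric vector of per-slice nodule probabilities.
#' @export
assemblePerspectiveFeatures <- function(scores) {
  if (is.null(dim(scores)) || ncol(scores) < 2L)
    stop("missing slice scores")
  if (anyNA(scores)) stop("missing slice score")
  unname(scores[, "nodule"])
}

#' Re-arrange the three perspective scores into the volume-module feature
#'
#' @param pScores named or ordered numeric of exactly three perspective
#'   nodule scores (V1, V2, V3).
#' @return Numeric vector of length 3 in fixed V1, V2, V3 order.
#' @export
assembleVolumeFeatures <- function(pScores) {
  if (length(pScores) != 3L || anyNA(pScores))
    stop("exactly one score per perspective (V1, V2, V3) is required")
  if (!is.null(names(pScores))) {
    if (!all(PERSPECTIVES %in% names(pScores)))
      stop("perspective scores must be named V1, V2, V3")
    pScores <- pScores[PERSPECTIVES]
  }
  unname(as.numeric(pScores))
}

#' Train a perspective fusion module
#'
#' Fits the single-hidden-layer feedforward classifier that maps one
#' perspective's slice-score vector to a perspective-level nodule
#' probability. The slice module that produced the features is frozen:
#' its parameters are not touched (modular isolation).
#'
#' @param features matrix, one row per VOI, \code{nSlices} columns of
#'   slice nodule scores.
#' @param labels VOI labels.
#' @param config see \code{\link{mpfConfig}}.
#' @param seed integer RNG seed.
#' @return A fitted fusion module.
#' @export
trainPerspectiveModule <- function(features, labels, config = mpfConfig(),
                                   seed = 1L) {
  trainScoreFusion(features, labels, config$hidden, config$maxit,
                   config$restarts, seed, config$decay)
}

#' Train the volume fusion module
#'
#' Fits the single-hidden-layer classifier over the three perspective
#' scores; the final decision is the argmax class (nodule probability
#' above 0.5).
#'
#' @param features matrix, one row per VOI, 3 columns (V1, V2, V3 scores).
#' @param labels VOI labels.
#' @param config see \code{\link{mpfConfig}}.
#' @param seed integer RNG seed.
#' @return A fitted fusion module.
#' @export
trainVolumeModule <- function(features, labels, config = mpfConfig(),
                              seed = 1L) {
  stopifnot(ncol(as.matrix(features)) == 3L)
  trainScoreFusion(features, labels, config$hidden, config$maxit,
                   config$restarts, seed, config$decay)
}

## ---- the modular training protocol -------------------------------------

recordStacks <- function(record, fspec) {
  if (is.null(fspec)) record$stacks
  else lapply(record$stacks, filterStack, spec = fspec)
}

sliceFeatureMatrix <- function(ms, stacks) {
  t(vapply(stacks, function(st)
    assemblePerspectiveFeatures(predictSliceScores(ms, st)),
    numeric(length(stacks[[1]]@slices))))
}

#' Train a complete multi-perspective hierarchical fusion model
#'
#' Executes the modular protocol level by level: (optionally) filter all
#' stacks into feature images, train the three slice CNNs on the slices
#' of their perspectives, freeze them and score the training stacks,
#' train the three perspective modules on the slice-score vectors, freeze
#' them, and train the volume module on the three perspective scores.
#' With a \code{featureSpec} this is the single-feature variant of the
#' scheme; with \code{featureSpec = NULL} it is the raw-image variant.
#'
#' @param records training records: each a list with \code{$stacks}
#'   (named list of the three \linkS4class{PerspectiveStack}) and
#'   \code{$label} ("nodule"/"non_nodule"); see
#'   \code{\link{phantomStackDataset}}.
#' @param config see \code{\link{mpfConfig}}.
#' @param seed integer RNG seed.
#' @param featureSpec optional \linkS4class{FilterSpec} front end.
#' @return A trained \linkS4class{HierarchicalModel}.
#' @export
trainMpf <- function(records, config = mpfConfig(), seed = 1L,
                     featureSpec = NULL) {
  if (length(records) == 0L) stop("stage slice: empty training set")
  labels <- vapply(records, function(r) r$label, character(1))
  stacksAll <- lapply(records, recordStacks, fspec = featureSpec)

  ms <- list(); msLogs <- list()
  for (p in PERSPECTIVES) {
    pStacks <- lapply(stacksAll, `[[`, p)
    ms[[p]] <- tryCatch(
      trainSliceModule(pStacks, labels, config$dcnn,
                       seed + match(p, PERSPECTIVES)),
      error = function(e) stop("stage slice (", p, "): ",
                               conditionMessage(e)))
    msLogs[[p]] <- ms[[p]]@trainingLog
  }

  mp <- list(); pScores <- matrix(NA_real_, length(records), 3L,
                                  dimnames = list(NULL, PERSPECTIVES))
  for (p in PERSPECTIVES) {
    feats <- sliceFeatureMatrix(ms[[p]], lapply(stacksAll, `[[`, p))
    mp[[p]] <- tryCatch(
      trainPerspectiveModule(feats, labels, config,
                             seed + 10L + match(p, PERSPECTIVES)),
      error = function(e) stop("stage perspective (", p, "): ",
                               conditionMessage(e)))
    pScores[, p] <- predictScoreFusion(mp[[p]], feats)
  }

  mv <- tryCatch(trainVolumeModule(pScores, labels, config, seed + 20L),
                 error = function(e) stop("stage volume: ",
                                          conditionMessage(e)))

  new("HierarchicalModel", sliceModules = ms, perspectiveModules = mp,
      volumeModule = mv, featureSpec = featureSpec,
      provenance = list(config = config, seed = seed,
                        featureFamily = if (is.null(featureSpec)) "raw"
                                        else featureSpec@family,
                        sliceTrainingLogs = msLogs,
                        nTrain = length(records)))
}

#' Predict all hierarchy levels for one VOI
#'
#' Runs the frozen hierarchy and returns every intermediate score so each
#' level can be evaluated: the per-slice score matrices of the three
#' perspectives, the three perspective scores, the volume score and the
#' final argmax label.
#'
#' @param model a trained \linkS4class{HierarchicalModel}.
#' @param stacks a record (list with \code{$stacks}) or the named list of
#'   three \linkS4class{PerspectiveStack} directly.
#' @return List with \code{sliceScores} (named list of matrices),
#'   \code{perspectiveScores} (named numeric(3)), \code{volumeScore}
#'   (nodule probability) and \code{label}.
#' @export
predictHierarchy <- function(model, stacks) {
  if (!is(model, "HierarchicalModel")) stop("untrained or invalid model")
  if (!is.null(stacks$stacks)) stacks <- stacks$stacks
  if (!is.null(model@featureSpec))
    stacks <- lapply(stacks, filterStack, spec = model@featureSpec)
  sliceScores <- lapply(PERSPECTIVES, function(p)
    predictSliceScores(model@sliceModules[[p]], stacks[[p]]))
  names(sliceScores) <- PERSPECTIVES
  pScores <- vapply(PERSPECTIVES, function(p)
    predictScoreFusion(model@perspectiveModules[[p]],
                       matrix(assemblePerspectiveFeatures(sliceScores[[p]]),
                              nrow = 1)),
    numeric(1))
  vScore <- predictScoreFusion(model@volumeModule,
                               matrix(assembleVolumeFeatures(pScores),
                                      nrow = 1))
  list(sliceScores = sliceScores, perspectiveScores = pScores,
       volumeScore = vScore,
       label = if (vScore >= 0.5) "nodule" else "non_nodule")
}

## ---- VolumeScorer interface --------------------------------------------

#' Volume-level nodule score of a record
#'
#' Generic used by the multi-feature top fusion: every member model maps
#' a record (its three perspective stacks) to a nodule probability.
#'
#' @param model a \linkS4class{VolumeScorer}.
#' @param record a dataset record (list with \code{$stacks}).
#' @return Numeric nodule probability in [0, 1].
#' @export
setGeneric("volumeScore", function(model, record) standardGeneric("volumeScore"))

#' @rdname volumeScore
#' @export
setMethod("volumeScore", "HierarchicalModel", function(model, record) {
  predictHierarchy(model, record)$volumeScore
})

#' @rdname volumeScore
#' @export
setMethod("volumeScore", "CallbackScorer", function(model, record) {
  model@fn(record)
})

#' Wrap a plain scoring function as a VolumeScorer
#'
#' @param fn function(record) returning a nodule probability in [0, 1].
#' @return A \linkS4class{CallbackScorer}.
#' @export
makeScorer <- function(fn) new("CallbackScorer", fn = fn)

memberScoreMatrix <- function(members, records) {
  vapply(members, function(m)
    vapply(records, function(r) volumeScore(m, r), numeric(1)),
    numeric(length(records)))
}

#' Train the multi-feature top fusion model
#'
#' Collects each member's volume-level nodule score on the training
#' records into an m-vector per VOI and trains an additional
#' single-hidden-layer fusion classifier over them. Members are used
#' frozen. All members must have been trained on the same training split;
#' when members carry a recorded training size it is checked.
#'
#' @param members list of trained \linkS4class{VolumeScorer} (typically
#'   the four feature-image hierarchies plus the raw-image one).
#' @param records training records (same split the members were trained on).
#' @param config see \code{\link{mpfConfig}}.
#' @param seed integer RNG seed.
#' @return A trained \linkS4class{MfmpfModel}.
#' @export
trainMfmpf <- function(members, records, config = mpfConfig(), seed = 1L) {
  stopifnot(length(members) >= 1L)
  nTrain <- unique(unlist(lapply(members, function(m)
    if (is(m, "HierarchicalModel")) m@provenance$nTrain)))
  if (length(nTrain) > 1L)
    stop("members were trained on mismatched splits")
  labels <- vapply(records, function(r) r$label, character(1))
  scores <- memberScoreMatrix(members, records)
  top <- trainScoreFusion(scores, labels, config$hidden, config$maxit,
                          config$restarts, seed, config$decay)
  new("MfmpfModel", members = members, topModule = top,
      provenance = list(config = config, seed = seed,
                        nMembers = length(members)))
}

#' Predict with the multi-feature fusion model
#'
#' Runs every member on the record, then the top fusion module on the
#' member volume scores.
#'
#' @param model a trained \linkS4class{MfmpfModel}.
#' @param record a dataset record.
#' @return List with \code{memberScores}, \code{topScore} and \code{label}.
#' @export
predictMfmpf <- function(model, record) {
  s <- vapply(model@members, function(m) volumeScore(m, record), numeric(1))
  p <- predictScoreFusion(model@topModule, matrix(s, nrow = 1))
  list(memberScores = s, topScore = p,
       label = if (p >= 0.5) "nodule" else "non_nodule")
}
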