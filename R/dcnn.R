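## The slice-level module: a compact deep CNN over 56x56 slices, one per
## perspective, trained separately (modular protocol). The numerical core
## lives in src/dcnn.cpp; this file holds the user-facing configuration,
## construction, training and inference surfaces plus the elementary
## building blocks (ReLU, softmax, cross-entropy).

#' Rectified linear activation
#'
#' \code{f(x) = max(0, x)}, applied element-wise.
#'
#' @param x numeric scalar, vector, matrix or array (finite).
#' @return Same shape as \code{x}.
#' @export
relu <- function(x) {
  stopifnot(all(is.finite(x)))
  pmax(x, 0)
}

#' Softmax over a vector of logits
#'
#' \deqn{\sigma(x_j) = e^{x_j} / \sum_k e^{x_k}} computed with the usual
#' max-shift for numerical stability; invariant to adding a constant to
#' all inputs.
#'
#' @param v finite numeric vector.
#' @return Probability vector of the same length (positive, sums to 1).
#' @export
softmax <- function(v) {
  stopifnot(all(is.finite(v)))
  e <- exp(v - max(v))
  e / sum(e)
}

#' Cross-entropy loss
#'
#' \deqn{L = -\sum_j t_j \log p_j} with predicted probabilities clipped to
#' \code{[1e-12, 1]} to guard against log(0). Non-negative; zero exactly
#' when the prediction puts probability 1 on the target class.
#'
#' @param t one-hot target vector.
#' @param p predicted probability vector of the same length.
#' @return Scalar loss.
#' @export
crossEntropy <- function(t, p) {
  stopifnot(length(t) == length(p))
  -sum(t * log(pmin(pmax(p, 1e-12), 1)))
}

#' Slice-module configuration
#'
#' Architecture: \code{length(convFilters)} blocks of 3x3 same-padding
#' convolution + ReLU + 2x2 max-pool (stride 2), with the filter count
#' doubling per layer from 8 to 64, followed by a 32-unit fully connected
#' ReLU layer and a softmax output over \code{nClasses}. For a 56x56 input
#' the spatial trace after the four pools is 56 -> 28 -> 14 -> 7 -> 3.
#' Training: Adam, cross-entropy loss, with early stopping on a held-out
#' validation fraction of the training slices.
#'
#' @param inputSize slice edge length in pixels (default 56).
#' @param convFilters filter counts per conv layer (default 8, 16, 32, 64;
#'   must double per layer starting at 8).
#' @param fcUnits fully connected layer width (default 32).
#' @param nClasses number of output classes (default 2).
#' @param lr Adam learning rate (default 1e-3).
#' @param batchSize minibatch size (default 32).
#' @param epochs maximum training epochs (default 30).
#' @param valFraction validation split fraction for early stopping
#'   (default 0.1; 0 disables early stopping).
#' @param patience early-stopping patience in epochs (default 5).
#' @return Named configuration list.
#' @export
dcnnConfig <- function(inputSize = 56L, convFilters = c(8L, 16L, 32L, 64L),
                       fcUnits = 32L, nClasses = 2L, lr = 1e-3,
                       batchSize = 32L, epochs = 30L, valFraction = 0.1,
                       patience = 5L) {
  if (convFilters[1] != 8L ||
      !all(convFilters[-1] == 2L * head(convFilters, -1L)))
    stop("configuration error: convFilters must double per layer from 8")
  if (fcUnits != 32L)
    stop("configuration error: the fully connected layer has 32 units")
  list(inputSize = as.integer(inputSize), convFilters = as.integer(convFilters),
       kernelSize = 3L, fcUnits = as.integer(fcUnits),
       nClasses = as.integer(nClasses), lr = lr,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       valFraction = valFraction, patience = as.integer(patience))
}

## spatial side length after the conv/pool blocks
finalSpatial <- function(inputSize, nBlocks) {
  s <- inputSize
  for (i in seq_len(nBlocks)) s <- s %/% 2L
  s
}

#' Build an untrained slice CNN
#'
#' Allocates seeded variance-scaled (He) random initial weights for the
#' configured architecture.
#'
#' @param config see \code{\link{dcnnConfig}}.
#' @param seed integer RNG seed for the initialization.
#' @return An untrained \linkS4class{SliceCnn}.
#' @export
buildDcnn <- function(config = dcnnConfig(), seed = 1L) {
  set.seed(seed)
  cf <- config$convFilters
  cin <- c(1L, head(cf, -1L))
  Wc <- vector("list", length(cf)); bc <- vector("list", length(cf))
  for (l in seq_along(cf)) {
    fanIn <- 9L * cin[l]
    Wc[[l]] <- matrix(rnorm(fanIn * cf[l], 0, sqrt(2 / fanIn)), fanIn, cf[l])
    bc[[l]] <- matrix(0, 1, cf[l])
  }
  s <- finalSpatial(config$inputSize, length(cf))
  flat <- s * s * cf[length(cf)]
  weights <- list(
    Wc = Wc, bc = bc,
    Wf = matrix(rnorm(config$fcUnits * flat, 0, sqrt(2 / flat)),
                config$fcUnits, flat),
    bf = numeric(config$fcUnits),
    Wo = matrix(rnorm(config$nClasses * config$fcUnits, 0,
                      sqrt(2 / config$fcUnits)),
                config$nClasses, config$fcUnits),
    bo = numeric(config$nClasses)
  )
  new("SliceCnn", weights = weights, config = config, trained = FALSE,
      trainingLog = data.frame())
}

## stack a list of matrices into an H x W x N array
imagesToArray <- function(images) {
  d <- dim(images[[1]])
  array(unlist(images, use.names = FALSE), dim = c(d[1], d[2], length(images)))
}

## flatten labeled PerspectiveStacks into slice images + inherited labels
stacksToSlices <- function(stacks, labels) {
  images <- unlist(lapply(stacks, stackSlices), recursive = FALSE)
  y <- rep(labels, vapply(stacks, function(s) length(s@slices), integer(1)))
  list(images = images, labels = y)
}

labelsToInt <- function(labels) {
  if (is.character(labels)) as.integer(labels == "nodule") else as.integer(labels)
}

#' Train a slice CNN on raw images
#'
#' Lower-level entry point used by \code{\link{trainSliceModule}} and by
#' controls that need direct access to the slice images (e.g. label
#' shuffling).
#'
#' @param images list of 2D matrices (all \code{inputSize} square).
#' @param labels "nodule"/"non_nodule" character vector or 0/1 integers
#'   (1 = nodule), one per image.
#' @param config see \code{\link{dcnnConfig}}.
#' @param seed integer RNG seed (initialization, splits and shuffling).
#' @return A trained \linkS4class{SliceCnn} with its training log.
#' @export
trainSliceCnn <- function(images, labels, config = dcnnConfig(), seed = 1L) {
  if (length(images) == 0L) stop("empty training set")
  stopifnot(length(images) == length(labels))
  model <- buildDcnn(config, seed)  # also seeds the RNG for the C++ loop
  X <- imagesToArray(images)
  y <- labelsToInt(labels)
  fit <- cnn_train_cpp(X, y, model@weights, config)
  new("SliceCnn", weights = fit$weights, config = config, trained = TRUE,
      trainingLog = fit$log)
}

#' Train the slice module of one perspective
#'
#' Every slice inherits its parent VOI's label; training uses only the
#' slices of the given stacks (one perspective).
#'
#' @param stacks list of \linkS4class{PerspectiveStack} of one perspective.
#' @param labels VOI labels parallel to \code{stacks}.
#' @param config see \code{\link{dcnnConfig}}.
#' @param seed integer RNG seed.
#' @return A trained \linkS4class{SliceCnn}.
#' @export
trainSliceModule <- function(stacks, labels, config = dcnnConfig(),
                             seed = 1L) {
  if (length(stacks) == 0L) stop("empty training set")
  sl <- stacksToSlices(stacks, labels)
  trainSliceCnn(sl$images, sl$labels, config, seed)
}

#' Class probabilities for each slice of a stack
#'
#' @param model a trained \linkS4class{SliceCnn}.
#' @param stack a \linkS4class{PerspectiveStack} (or list of 2D matrices).
#' @return Matrix with one row per slice and columns
#'   \code{c("non_nodule", "nodule")}; each row sums to 1. The nodule
#'   column is the scalar slice score.
#' @export
predictSliceScores <- function(model, stack) {
  if (!model@trained) stop("model is not trained")
  images <- if (is(stack, "PerspectiveStack")) stack@slices else stack
  d <- dim(images[[1]])
  if (d[1] != model@config$inputSize || d[2] != model@config$inputSize)
    stop("slice shape does not match the model input size")
  probs <- cnn_predict_cpp(model@weights, imagesToArray(images))
  colnames(probs) <- c("non_nodule", "nodule")
  probs
}
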