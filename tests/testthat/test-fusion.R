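fakeScores <- function(n, informative = TRUE, seed = 1, len = 6L) {
  set.seed(seed)
  labels <- rep(c("nodule", "non_nodule"), length.out = n)
  x <- t(vapply(labels, function(l) {
    if (informative && l == "nodule") runif(len, 0.6, 1)
    else if (informative) runif(len, 0, 0.4)
    else runif(len)
  }, numeric(len)))
  list(x = x, labels = labels)
}

test_that("score re-arrangement preserves slice order and arity", {
  sc10 <- cbind(non_nodule = seq(0, 0.9, 0.1), nodule = seq(1, 0.1, -0.1))
  expect_length(assemblePerspectiveFeatures(sc10), 10)
  sc6 <- sc10[1:6, ]
  expect_length(assemblePerspectiveFeatures(sc6), 6)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(assemblePerspectiveFeatures(sc6[perm, ]),
               assemblePerspectiveFeatures(sc6)[perm])
  expect_error(assemblePerspectiveFeatures(c(0.1, 0.2)), "missing")

  v <- assembleVolumeFeatures(c(V2 = 0.8, V1 = 0.9, V3 = 0.95))
  expect_equal(v, c(0.9, 0.8, 0.95))
  expect_length(assembleVolumeFeatures(c(0.9, 0.8, 0.95)), 3)
  expect_error(assembleVolumeFeatures(c(0.9, 0.8)), "exactly one score")
})

test_that("the perspective module separates separable slice-score inputs", {
  accs <- vapply(1:3, function(s) {
    tr <- fakeScores(120, seed = 50 + s)
    te <- fakeScores(60, seed = 150 + s)
    mp <- trainPerspectiveModule(tr$x, tr$labels, mpfConfig(), seed = s)
    p <- hierfusion:::predictScoreFusion(mp, te$x)
    mean((p >= 0.5) == (te$labels == "nodule"))
  }, numeric(1))
  expect_gte(mean(accs), 0.95)

  # outputs are probabilities
  tr <- fakeScores(40, seed = 2)
  mp <- trainPerspectiveModule(tr$x, tr$labels, mpfConfig(), seed = 2)
  p <- hierfusion:::predictScoreFusion(mp, fakeScores(20, seed = 3)$x)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(hierfusion:::predictScoreFusion(mp, matrix(0.5, 2, 4)),
               "does not match")
})

test_that("the volume module fuses informative and adversarial perspectives", {
  mkVol <- function(n, seed, adversarial = FALSE) {
    set.seed(seed)
    labels <- rep(c("nodule", "non_nodule"), length.out = n)
    y <- as.integer(labels == "nodule")
    x <- cbind(y + rnorm(n, 0, 0.02), y + rnorm(n, 0, 0.02),
               if (adversarial) 1 - y + rnorm(n, 0, 0.02)
               else y + rnorm(n, 0, 0.02))
    list(x = pmin(pmax(x, 0), 1), labels = labels)
  }
  # perfectly informative inputs
  tr <- mkVol(200, 1); te <- mkVol(100, 2)
  mv <- trainVolumeModule(tr$x, tr$labels, mpfConfig(), seed = 1)
  acc <- mean((hierfusion:::predictScoreFusion(mv, te$x) >= 0.5) ==
              (te$labels == "nodule"))
  expect_gte(acc, 0.99)

  # one adversarial perspective is down-weighted
  accs <- vapply(1:3, function(s) {
    tr <- mkVol(200, 10 + s, adversarial = TRUE)
    te <- mkVol(100, 20 + s, adversarial = TRUE)
    mv <- trainVolumeModule(tr$x, tr$labels, mpfConfig(), seed = s)
    mean((hierfusion:::predictScoreFusion(mv, te$x) >= 0.5) ==
         (te$labels == "nodule"))
  }, numeric(1))
  expect_gte(mean(accs), 0.95)

  # seeded determinism
  mv2 <- trainVolumeModule(tr$x, tr$labels, mpfConfig(), seed = 3)
  mv3 <- trainVolumeModule(tr$x, tr$labels, mpfConfig(), seed = 3)
  expect_identical(mv2$fit$wts, mv3$fit$wts)
})

test_that("the full hierarchy trains modularly and reports every level", {
  b <- easyBenchmark()
  recs <- b$records[b$split$train][1:30]
  cfg <- mpfConfig(dcnn = dcnnConfig(epochs = 2, patience = 2))
  model <- trainMpf(recs, cfg, seed = 5)

  expect_s4_class(model, "HierarchicalModel")
  expect_named(sliceModules(model), c("V1", "V2", "V3"))
  expect_identical(model@provenance$featureFamily, "raw")

  pred <- predictHierarchy(model, b$records[[1]])
  expect_named(pred$sliceScores, c("V1", "V2", "V3"))
  for (p in c("V1", "V2", "V3"))
    expect_identical(dim(pred$sliceScores[[p]]), c(6L, 2L))
  expect_length(pred$perspectiveScores, 3)
  expect_true(all(pred$perspectiveScores >= 0 & pred$perspectiveScores <= 1))
  expect_length(pred$volumeScore, 1)
  expect_identical(pred$label,
                   if (pred$volumeScore >= 0.5) "nodule" else "non_nodule")

  # deterministic inference
  pred2 <- predictHierarchy(model, b$records[[1]])
  expect_identical(pred, pred2)

  expect_error(trainMpf(list(), cfg), "empty")
})

test_that("a feature-image front end runs end-to-end and is recorded", {
  b <- easyBenchmark()
  recs <- b$records[b$split$train][1:16]
  cfg <- mpfConfig(dcnn = dcnnConfig(epochs = 1, valFraction = 0, patience = 1))
  sp <- filterSpec("trilateral")
  model <- trainMpf(recs, cfg, seed = 8, featureSpec = sp)
  expect_identical(model@provenance$featureFamily, "trilateral")
  expect_identical(featureSpec(model)@family, "trilateral")
  pred <- predictHierarchy(model, recs[[1]])
  expect_true(is.finite(pred$volumeScore))
})

test_that("top fusion handles redundancy and rejects mismatched members", {
  b <- easyBenchmark()
  tr <- b$records[b$split$train][1:80]
  te <- b$records[b$split$test][1:60]
  informative <- makeScorer(function(r)
    0.1 + 0.8 * (r$label == "nodule") + 0.1 * hashScore(r$objectId, 1))

  # all members identical: fusion keeps the member's accuracy
  memberAcc <- mean(vapply(te, function(r)
    (volumeScore(informative, r) >= 0.5) == (r$label == "nodule"),
    logical(1)))
  accs <- vapply(1:3, function(s) {
    mf <- trainMfmpf(list(informative, informative, informative), tr,
                     mpfConfig(), seed = s)
    mean(vapply(te, function(r)
      predictMfmpf(mf, r)$label == r$label, logical(1)))
  }, numeric(1))
  expect_gte(mean(accs), memberAcc - 0.02)

  # member count fixes the top-module input length
  members5 <- c(list(informative), lapply(2:5, function(i)
    makeScorer(local({ii <- i; function(r) hashScore(r$objectId, ii)}))))
  mf5 <- trainMfmpf(members5, tr, mpfConfig(), seed = 1)
  expect_identical(mf5@topModule$inputLength, 5L)
  expect_length(predictMfmpf(mf5, te[[1]])$memberScores, 5)

  # members trained on mismatched splits are rejected
  dummyCnn <- new("SliceCnn", weights = list(), config = list(),
                  trained = FALSE, trainingLog = data.frame())
  mkFake <- function(n) new("HierarchicalModel",
    sliceModules = list(V1 = dummyCnn, V2 = dummyCnn, V3 = dummyCnn),
    perspectiveModules = list(V1 = NULL, V2 = NULL, V3 = NULL),
    volumeModule = NULL, featureSpec = NULL,
    provenance = list(nTrain = n))
  expect_error(trainMfmpf(list(mkFake(100), mkFake(200)), tr), "mismatched")
})
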