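test_that("heaviside treats zero as positive", {
  expect_identical(heaviside(0), 1)
  expect_identical(heaviside(-1e-12), 0)
  expect_identical(heaviside(5), 1)
  expect_error(heaviside(NaN), "finite")
})

test_that("a single stump yields the expected two-piece score curve", {
  feat <- "F1"
  ens <- new("StumpEnsemble",
             models = list(list(bias = 0, seed = 1L,
               stumps = data.frame(feature = feat, theta = 1,
                                   vLeft = 0.5, vRight = -0.5,
                                   gain = 2))),
             config = ensembleConfig(1),
             featureRanges = matrix(c(-1, 3), 2,
                                    dimnames = list(c("lo", "hi"), feat)),
             masterSeed = 1L)
  cur <- scoreCurve(ens, feat)
  expect_equal(scoreCurveValue(cur, c(0, 0.999, 1, 2)),
               c(0.5, 0.5, -0.5, -0.5))
})

test_that("duplicating every model leaves score curves unchanged", {
  set.seed(1)
  ens <- randomEnsemble(5, 8, paste0("F", 1:3))
  doubled <- ens
  doubled@models <- c(ens@models, ens@models)
  doubled@config <- ensembleConfig(10)
  xs <- runif(200, -3, 3)
  for (f in paste0("F", 1:3))
    expect_equal(scoreCurveValue(scoreCurve(doubled, f), xs),
                 scoreCurveValue(scoreCurve(ens, f), xs))
})

test_that("score curves match the brute-force stump summation", {
  set.seed(2)
  ens <- randomEnsemble(20, 15, paste0("F", 1:4))
  for (f in c("F1", "F3")) {
    cur <- scoreCurve(ens, f)
    xs <- c(runif(200, -3, 3), cur@breaks)  # include exact breakpoints
    brute <- vapply(xs, function(x) bruteCurveValue(ens, f, x),
                    numeric(1))
    expect_lt(max(abs(scoreCurveValue(cur, xs) - brute)), 1e-12)
  }
})

test_that("summed score curves equal the mean bias-free margin", {
  set.seed(3)
  feats <- paste0("F", 1:4)
  ens <- randomEnsemble(10, 12, feats)
  curves <- lapply(feats, function(f) scoreCurve(ens, f))
  for (i in 1:50) {
    x <- runif(4, -3, 3); names(x) <- feats
    additive <- sum(vapply(seq_along(feats), function(j)
      scoreCurveValue(curves[[j]], x[feats[j]]), numeric(1)))
    expect_lt(abs(additive - ensembleMargin(ens, x)), 1e-9)
    expect_lt(abs(additive - bruteMargin(ens, x)), 1e-9)
  }
})

test_that("fitting an exactly sampled sigmoid recovers its parameters", {
  truth <- list(A = 1, t = 0, k = 2, m = 0.5)
  xs <- seq(-5, 5, length.out = 400)
  ys <- truth$A * plogis(-truth$k * (xs - truth$t)) - truth$m
  # encode the sampled sigmoid as a fine staircase
  cur <- new("ScoreCurve", feature = "F", breaks = xs[-1],
             values = ys, weights = rep(1, length(xs) - 1),
             domain = c(-5, 5))
  fit <- fitSigmoid(cur, gridSize = 400L)
  expect_lt(abs(fit@A - 1), 1e-3)
  expect_lt(abs(fit@t - 0), 1e-3)
  expect_lt(abs(fit@k - 2), 1e-3)
  expect_lt(abs(fit@m - 0.5), 1e-3)
})

test_that("a constant curve is fit by a degenerate flat sigmoid", {
  cur <- new("ScoreCurve", feature = "F", breaks = numeric(),
             values = 0.37, weights = numeric(), domain = c(0, 2))
  fit <- fitSigmoid(cur)
  xs <- seq(0, 2, length.out = 50)
  expect_lt(max(abs(sigmoidValue(fit, xs) - 0.37)), 1e-6)
})

test_that("a decreasing staircase is fit by a decreasing sigmoid (k > 0)", {
  cur <- new("ScoreCurve", feature = "F", breaks = c(0.5, 1, 1.5),
             values = c(0.4, 0.15, -0.1, -0.4),
             weights = c(1, 1, 1), domain = c(0, 2))
  fit <- fitSigmoid(cur)
  expect_gt(fit@k, 0)
  xs <- seq(0, 2, length.out = 100)
  expect_true(all(diff(sigmoidValue(fit, xs)) <= 1e-12))
})

test_that("model construction takes the top-k ranked features", {
  set.seed(4)
  gt <- groundTruthSOS()
  d <- sampleFromGroundTruth(gt, 800, seed = 5, nNuisance = 10)
  ens <- trainStumpEnsemble(d$features, ensembleConfig(5, 20), seed = 6)
  rk <- gainRanking(ens)
  mod <- buildSOSModel(ens, 4)
  expect_identical(modelFeatures(mod), rk$feature[1:4])
  mod1 <- buildSOSModel(ens, 1)
  expect_length(modelFeatures(mod1), 1L)
  expect_error(buildSOSModel(ens, nrow(rk) + 1L), "between 1")
})

test_that("predictions are exact sums of sigmoid evaluations", {
  set.seed(5)
  gt <- groundTruthSOS()
  mod <- gt@model
  X <- matrix(runif(200 * 4, 0, 2), 200,
              dimnames = list(NULL, modelFeatures(mod)))
  pr <- predict(mod, X)
  fits <- sigmoidFits(mod)
  for (i in c(1, 57, 200)) {
    byHand <- sum(vapply(names(fits), function(f) {
      fit <- fits[[f]]
      fit@A / (1 + exp(fit@k * (X[i, f] - fit@t))) - fit@m
    }, numeric(1)))
    expect_lt(abs(pr$sum[i] - byHand), 1e-12)
  }
  expect_identical(pr$prediction, heaviside(pr$sum))
})

test_that("a zero score sum predicts an event and missing features error", {
  fit <- PolarSOS:::.newSigmoidFit(A = 0, t = 0, k = 1, m = 0,
                                   rmse = 0, domain = c(-1, 1))
  mod <- new("SumOfSigmoidsModel", featureNames = "F1", fits = list(fit),
             provenance = list())
  pr <- predict(mod, c(F1 = 0.3))        # constant zero score
  expect_identical(pr$prediction, 1)
  expect_error(predict(mod, c(F2 = 1)), "missing model feature")
  expect_error(predict(mod, c(F1 = NA_real_)), "non-finite")
})

test_that("serialization round-trips predictions exactly", {
  set.seed(6)
  gt <- groundTruthSOS()
  d <- sampleFromGroundTruth(gt, 600, seed = 7, nNuisance = 8)
  ens <- trainStumpEnsemble(d$features, ensembleConfig(4, 15), seed = 8)
  mod <- buildSOSModel(ens, 3)
  path <- tempfile(fileext = ".json")
  writeSOSModel(mod, path)
  mod2 <- readSOSModel(path)
  X <- matrix(runif(100 * 3, 0, 2.5), 100,
              dimnames = list(NULL, modelFeatures(mod)))
  expect_identical(predict(mod2, X), predict(mod, X))
})

test_that("pruning drops only small-range terms and needs a survivor", {
  gt <- groundTruthSOS()
  mod <- gt@model
  flat <- PolarSOS:::.newSigmoidFit(A = 1e-6, t = 1, k = 1, m = 0,
                                    rmse = 0, domain = c(0, 2))
  mod@featureNames <- c(mod@featureNames, "REST_S1_MEAN")
  mod@fits <- c(mod@fits, flat)
  expect_identical(pruneSmallRange(mod, 0), mod)
  pruned <- pruneSmallRange(mod, 1e-3)
  expect_false("REST_S1_MEAN" %in% modelFeatures(pruned))
  expect_length(modelFeatures(pruned), 4L)
  # a dominated near-flat term barely changes predictions
  set.seed(7)
  X <- matrix(runif(2000 * 5, 0, 2.5), 2000,
              dimnames = list(NULL, modelFeatures(mod)))
  disagree <- mean(predict(mod, X)$prediction !=
                   predict(pruned, X[, 1:4])$prediction)
  expect_lt(disagree, 0.01)
  expect_error(pruneSmallRange(mod, 1e6), "every sigmoid")
})

test_that("accuracy-vs-k traces are well-formed and favour the true k", {
  set.seed(8)
  gt3 <- groundTruthSOS(features = c("STRESS_S14_MIN", "STRESS_S10_MIN",
                                     "STRESS_S15_MIN"),
                        A = c(1, 0.9, 0.8), t = c(1, 1.1, 0.9),
                        k = c(60, 70, 60), m = 0.6 * c(1, 0.9, 0.8))
  acc1 <- acc3 <- numeric(0)
  for (i in 1:9) {
    d <- sampleFromGroundTruth(gt3, 900, seed = 20 + i, nNuisance = 10)
    sp <- splitTrainTest(d$features, 0.25, seed = 40 + i)
    ens <- trainStumpEnsemble(sp$train, ensembleConfig(8, 20),
                              seed = 60 + i)
    curve <- accuracyVsK(ens, sp$test, kMax = 3)
    expect_identical(curve$k, 1:3)
    expect_true(all(curve$accuracy >= 0 & curve$accuracy <= 1))
    acc1 <- c(acc1, curve$accuracy[1])
    acc3 <- c(acc3, curve$accuracy[3])
  }
  expect_gte(median(acc3), median(acc1))
  single <- accuracyVsK(ens, sp$test, kMax = 1)
  expect_identical(nrow(single), 1L)
})

test_that("ensembles predict more stably across seeds than single models", {
  set.seed(9)
  gt <- groundTruthSOS()
  d <- sampleFromGroundTruth(gt, 1200, seed = 1, nNuisance = 6)
  grid <- matrix(runif(400 * 4, 0.2, 2.4), 400,
                 dimnames = list(NULL, modelFeatures(gt@model)))
  predsFor <- function(nm) lapply(1:8, function(s) {
    ens <- trainStumpEnsemble(d$features, ensembleConfig(nm, 15),
                              seed = 500 + s)
    predict(buildSOSModel(ens, 4), grid)$prediction
  })
  disagreement <- function(preds) {
    pairs <- utils::combn(length(preds), 2)
    mean(apply(pairs, 2, function(p)
      mean(preds[[p[1]]] != preds[[p[2]]])))
  }
  dEns <- disagreement(predsFor(10))
  dSingle <- disagreement(predsFor(1))
  expect_lt(dEns, dSingle)
})
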