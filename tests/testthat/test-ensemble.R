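test_that("the ensemble holds one stump list per configured model", {
  set.seed(1)
  se <- noiseFeatureSE(200, 8, prevalence = 0.2)
  ens <- trainStumpEnsemble(se, ensembleConfig(nModels = 5, nrounds = 8),
                            seed = 2)
  expect_identical(nModels(ens), 5L)
  for (m in ens@models) {
    expect_true(all(c("feature", "theta", "vLeft", "vRight", "gain") %in%
                      names(m$stumps)))
    expect_true(all(m$stumps$gain >= 0))
  }
})

test_that("a single stump on separable data splits the classes", {
  set.seed(2)
  se <- separableSE(120, threshold = 0.5)
  ens <- trainStumpEnsemble(se, ensembleConfig(nModels = 1, nrounds = 1,
                                               targetPosFraction = 0.4),
                            seed = 3)
  st <- ens@models[[1]]$stumps
  expect_identical(nrow(st), 1L)
  expect_identical(st$feature, "SEP")
  x <- t(assay(se))
  pred <- heaviside(ensembleMargin(ens, x))
  expect_identical(as.integer(pred), outcomesOf(se))
})

test_that("training is deterministic under the master seed", {
  set.seed(3)
  se <- noiseFeatureSE(150, 6, prevalence = 0.25)
  e1 <- trainStumpEnsemble(se, ensembleConfig(3, 6), seed = 9)
  e2 <- trainStumpEnsemble(se, ensembleConfig(3, 6), seed = 9)
  expect_identical(lapply(e1@models, `[[`, "stumps"),
                   lapply(e2@models, `[[`, "stumps"))
})

test_that("extracted stumps reproduce the boosted model's raw margin", {
  set.seed(4)
  n <- 300
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(X[, 1] - 0.7 * X[, 3] + rnorm(n, sd = 0.4) > 0)
  dm <- xgboost::xgb.DMatrix(X, label = y)
  bst <- xgboost::xgb.train(
    params = list(max_depth = 1, eta = 0.3,
                  objective = "binary:logistic", base_score = 0.5,
                  nthread = 1),
    data = dm, nrounds = 25, verbose = 0)
  st <- extractStumps(bst)
  bias <- attr(st, "bias")
  Xnew <- matrix(rnorm(1000 * 4), 1000,
                 dimnames = list(NULL, paste0("f", 1:4)))
  manual <- bias + vapply(seq_len(1000), function(i) {
    sum(ifelse(Xnew[i, st$feature] >= st$theta, st$vRight, st$vLeft))
  }, numeric(1))
  margin <- predict(bst, xgboost::xgb.DMatrix(Xnew), outputmargin = TRUE)
  expect_lt(max(abs(manual - margin)), 1e-6)
})

test_that("gain ranking finds the causal feature and ignores unused ones", {
  hits <- 0L
  for (i in 1:15) {
    set.seed(100 + i)
    se <- separableSE(160, threshold = 0.2)
    ens <- trainStumpEnsemble(se, ensembleConfig(4, 10), seed = 100 + i)
    rk <- gainRanking(ens)
    hits <- hits + as.integer(rk$feature[1] == "SEP")
    expect_true(all(rk$gain > 0))
    expect_true(all(diff(rk$gain) <= 1e-12))
  }
  expect_gte(hits, 14L)
})

test_that("the ranking is invariant to model order", {
  set.seed(5)
  se <- noiseFeatureSE(200, 6, prevalence = 0.25)
  ens <- trainStumpEnsemble(se, ensembleConfig(6, 8), seed = 1)
  shuffled <- ens
  shuffled@models <- ens@models[c(4, 2, 6, 1, 5, 3)]
  expect_identical(gainRanking(ens), gainRanking(shuffled))
})

test_that("margins follow the Heaviside boundary convention", {
  feat <- "F1"
  ens <- new("StumpEnsemble",
             models = list(list(bias = 0, seed = 1L,
               stumps = data.frame(feature = feat, theta = 2,
                                   vLeft = -0.3, vRight = 0.4,
                                   gain = 1))),
             config = ensembleConfig(1),
             featureRanges = matrix(c(0, 4), 2,
                                    dimnames = list(c("lo", "hi"), feat)),
             masterSeed = 1L)
  expect_equal(ensembleMargin(ens, c(F1 = 2)), 0.4)     # H(0) = 1
  expect_equal(ensembleMargin(ens, c(F1 = 2 - 1e-9)), -0.3)
  expect_error(ensembleMargin(ens, c(F2 = 1)), "missing feature")
})

test_that("an ensemble with no stumps has zero margin", {
  ens <- new("StumpEnsemble",
             models = list(list(bias = 0, seed = 1L,
               stumps = data.frame(feature = character(),
                                   theta = numeric(), vLeft = numeric(),
                                   vRight = numeric(), gain = numeric()))),
             config = ensembleConfig(1),
             featureRanges = matrix(c(0, 1), 2,
                                    dimnames = list(c("lo", "hi"), "F1")),
             masterSeed = 1L)
  expect_equal(ensembleMargin(ens, c(F1 = 0.5)), 0)
  expect_identical(nrow(gainRanking(ens)), 0L)
})

test_that("ensembles round-trip through JSON", {
  set.seed(6)
  se <- noiseFeatureSE(150, 5, prevalence = 0.25)
  ens <- trainStumpEnsemble(se, ensembleConfig(3, 6), seed = 4)
  path <- tempfile(fileext = ".json")
  writeStumpEnsemble(ens, path)
  ens2 <- readStumpEnsemble(path)
  x <- rnorm(5); names(x) <- paste0("F", 1:5)
  expect_identical(ensembleMargin(ens2, x), ensembleMargin(ens, x))
  expect_identical(gainRanking(ens2), gainRanking(ens))
})
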