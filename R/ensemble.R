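#' Ensemble training configuration
#'
#' Defaults: 100 models, 50 boosting rounds each, learning rate 0.3, no
#' row/column subsampling, binary logistic objective with raw-margin leaf
#' scores, and per-model stratification to 40% positives.
#'
#' @param nModels number of independently stratified models N.
#' @param nrounds boosting rounds per model.
#' @param eta learning rate in (0, 1].
#' @param subsample,colsampleBytree optional subsampling fractions.
#' @param targetPosFraction stratification target positive fraction.
#' @return an [EnsembleConfig-class].
#' @export
ensembleConfig <- function(nModels = 100L, nrounds = 50L, eta = 0.3,
                           subsample = 1, colsampleBytree = 1,
                           targetPosFraction = 0.4) {
  new("EnsembleConfig", nModels = as.integer(nModels),
      nrounds = as.integer(nrounds), eta = eta, subsample = subsample,
      colsampleBytree = colsampleBytree,
      targetPosFraction = targetPosFraction)
}

#' Extract the stumps of a depth-one boosted model
#'
#' Parses a fitted `xgb.Booster` tree dump into a stump table. Leaf
#' orientation follows the tree convention "x < theta goes left": `vLeft`
#' is the value added when x < theta and `vRight` when x >= theta, matching
#' the Heaviside convention H(0) = 1. Trees reduced to a single leaf
#' contribute to the returned `"bias"` attribute instead of a stump row.
#'
#' @param booster a fitted `xgb.Booster` trained with `max_depth = 1`.
#' @return data.frame with columns `feature`, `theta`, `vLeft`, `vRight`,
#'   `gain`, one row per stump, with attribute `bias` (sum of leaf-only
#'   tree values). A model with no trees yields zero rows.
#' @export
extractStumps <- function(booster) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  empty <- data.frame(feature = character(), theta = numeric(),
                      vLeft = numeric(), vRight = numeric(),
                      gain = numeric())
  if (!nrow(dt)) return(structure(empty, bias = 0))
  bias <- 0
  rows <- vector("list", length(unique(dt$Tree)))
  for (tr in unique(dt$Tree)) {
    sub <- dt[dt$Tree == tr, ]
    if (nrow(sub) > 3L)
      stop("tree ", tr, " has depth > 1; the ensemble contract requires ",
           "depth-one models")
    root <- sub[sub$Node == 0L, ]
    if (root$Feature == "Leaf") {
      bias <- bias + root$Gain
      next
    }
    leaves <- sub[sub$Feature == "Leaf", ]
    if (nrow(leaves) != 2L)
      stop("tree ", tr, " is not a stump")
    rows[[tr + 1L]] <- data.frame(
      feature = root$Feature, theta = root$Split,
      vLeft = leaves$Gain[match(root$Yes, leaves$ID)],
      vRight = leaves$Gain[match(root$No, leaves$ID)],
      gain = root$Gain)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  structure(out, bias = bias)
}

#' Train an ensemble of depth-one boosted models
#'
#' Trains `config@nModels` gradient-boosted models of maximum depth one,
#' each on its own stratified undersample of the training set (model j uses
#' seed `seed + j` for both the stratification draw and the booster), and
#' parses every model into its stump list. A model in which boosting finds
#' no usable split is retained as an empty model with a message.
#'
#' @param train feature table (SummarizedExperiment with `MACE`).
#' @param config an [EnsembleConfig-class].
#' @param seed master integer seed; the whole ensemble is reproducible from
#'   it.
#' @return a [StumpEnsemble-class].
#' @export
trainStumpEnsemble <- function(train, config = ensembleConfig(),
                               seed = 1L) {
  X <- .featureMatrix(train)
  y <- .outcomes(train)
  if (length(unique(y)) < 2L) stop("training set needs both classes")
  ranges <- rbind(lo = apply(X, 2, min), hi = apply(X, 2, max))
  seed <- as.integer(seed)
  models <- vector("list", config@nModels)
  for (j in seq_len(config@nModels)) {
    sj <- seed + j
    strat <- withCallingHandlers(
      stratifyUndersample(train, config@targetPosFraction, seed = sj),
      warning = function(w) invokeRestart("muffleWarning"))
    idx <- strat@indices
    dm <- xgboost::xgb.DMatrix(X[idx, , drop = FALSE], label = y[idx])
    # exact split enumeration keeps thresholds at midpoints between
    # observed values, so the x >= theta stump semantics are faithful
    params <- list(max_depth = 1, eta = config@eta,
                   tree_method = "exact",
                   objective = "binary:logistic", base_score = 0.5,
                   subsample = config@subsample,
                   colsample_bytree = config@colsampleBytree,
                   seed = sj, nthread = 1)
    bst <- xgboost::xgb.train(params = params, data = dm,
                              nrounds = config@nrounds, verbose = 0)
    stumps <- extractStumps(bst)
    if (!nrow(stumps))
      message("model ", j, " produced no usable splits; kept empty")
    models[[j]] <- list(bias = attr(stumps, "bias"), seed = sj,
                        stumps = `attr<-`(stumps, "bias", NULL))
  }
  new("StumpEnsemble", models = models, config = config,
      featureRanges = ranges, masterSeed = seed)
}

# all stumps of the ensemble in one table (no bias terms)
.allStumps <- function(ensemble) {
  do.call(rbind, lapply(ensemble@models, `[[`, "stumps"))
}

#' @describeIn trainStumpEnsemble number of member models
#' @param ensemble a [StumpEnsemble-class].
#' @export
setMethod("nModels", "StumpEnsemble",
          function(ensemble) length(ensemble@models))

#' Gain-sum feature ranking
#'
#' Sums the split gain of every feature over all stumps of all member
#' models and sorts features by decreasing summed gain (ties broken
#' lexicographically). Features never split on are omitted.
#'
#' @param ensemble a [StumpEnsemble-class].
#' @return data.frame with columns `feature` and `gain`, ordered by
#'   decreasing gain.
#' @export
setMethod("gainRanking", "StumpEnsemble", function(ensemble) {
  st <- .allStumps(ensemble)
  if (is.null(st) || !nrow(st))
    return(data.frame(feature = character(), gain = numeric()))
  g <- tapply(st$gain, st$feature, sum)
  out <- data.frame(feature = names(g), gain = as.numeric(g))
  out <- out[out$gain != 0, , drop = FALSE]
  out <- out[order(-out$gain, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' Mean raw margin of the ensemble (bias excluded)
#'
#' Evaluates `(1/N) * sum over models and stumps of
#' (vRight * H(x - theta) + vLeft * (1 - H(x - theta)))`. Per-model bias
#' terms are excluded; the decision threshold of the derived
#' sum-of-sigmoids model refers to this bias-free sum.
#'
#' @param ensemble a [StumpEnsemble-class].
#' @param x named numeric vector, or a patients x features matrix with
#'   column names, covering every feature any stump uses.
#' @return numeric margin(s).
#' @export
setMethod("ensembleMargin", "StumpEnsemble", function(ensemble, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  st <- .allStumps(ensemble)
  N <- nModels(ensemble)
  if (is.null(st) || !nrow(st)) return(numeric(nrow(x)))
  missing <- setdiff(unique(st$feature), colnames(x))
  if (length(missing))
    stop("missing feature value(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  out <- numeric(nrow(x))
  for (f in unique(st$feature)) {
    sf <- st[st$feature == f, ]
    xv <- x[, f]
    fire <- outer(xv, sf$theta, `>=`)     # H(x - theta)
    out <- out +
      (fire %*% sf$vRight + (!fire) %*% sf$vLeft)[, 1L]
  }
  unname(out) / N
})

#' Serialize / restore a stump ensemble as JSON
#'
#' The JSON layout is self-contained and library-independent:
#' `[{bias, seed, stumps: [{feature, theta, v_left, v_right, gain}]}, ...]`
#' plus the configuration and feature ranges.
#'
#' @param ensemble a [StumpEnsemble-class].
#' @param path JSON file path.
#' @return `readStumpEnsemble` returns the restored
#'   [StumpEnsemble-class]; `writeStumpEnsemble` returns `path` invisibly.
#' @export
writeStumpEnsemble <- function(ensemble, path) {
  cfg <- ensemble@config
  obj <- list(
    config = list(n_models = cfg@nModels, nrounds = cfg@nrounds,
                  eta = cfg@eta, subsample = cfg@subsample,
                  colsample_bytree = cfg@colsampleBytree,
                  target_pos_fraction = cfg@targetPosFraction),
    master_seed = ensemble@masterSeed,
    feature_ranges = list(feature = colnames(ensemble@featureRanges),
                          lo = unname(ensemble@featureRanges["lo", ]),
                          hi = unname(ensemble@featureRanges["hi", ])),
    models = lapply(ensemble@models, function(m)
      list(bias = m$bias, seed = m$seed,
           stumps = list(feature = m$stumps$feature,
                         theta = m$stumps$theta,
                         v_left = m$stumps$vLeft,
                         v_right = m$stumps$vRight,
                         gain = m$stumps$gain))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeStumpEnsemble
#' @export
readStumpEnsemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- ensembleConfig(obj$config$n_models, obj$config$nrounds,
                        obj$config$eta, obj$config$subsample,
                        obj$config$colsample_bytree,
                        obj$config$target_pos_fraction)
  ranges <- rbind(lo = obj$feature_ranges$lo, hi = obj$feature_ranges$hi)
  colnames(ranges) <- obj$feature_ranges$feature
  models <- lapply(obj$models, function(m) {
    st <- m$stumps
    list(bias = m$bias, seed = m$seed,
         stumps = data.frame(feature = as.character(unlist(st$feature)),
                             theta = as.numeric(unlist(st$theta)),
                             vLeft = as.numeric(unlist(st$v_left)),
                             vRight = as.numeric(unlist(st$v_right)),
                             gain = as.numeric(unlist(st$gain))))
  })
  new("StumpEnsemble", models = models, config = cfg,
      featureRanges = ranges, masterSeed = as.integer(obj$master_seed))
}

setMethod("show", "StumpEnsemble", function(object) {
  st <- .allStumps(object)
  cat(sprintf("StumpEnsemble: %d depth-one models, %d stumps, %d features\n",
              nModels(object), if (is.null(st)) 0L else nrow(st),
              if (is.null(st)) 0L else length(unique(st$feature))))
  cat(sprintf("  master seed %d, %d boosting rounds, eta %.2f\n",
              object@masterSeed, object@config@nrounds, object@config@eta))
})
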