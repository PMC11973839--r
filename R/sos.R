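#' @importFrom stats plogis runif setNames
NULL

#' Compute a feature's input-variable score curve
#'
#' Averages the additive contribution of one feature over the ensemble:
#' every stump on that feature contributes
#' `(vRight * H(x - theta) + vLeft * (1 - H(x - theta))) / N`, so the curve
#' is piecewise constant with a step at every distinct threshold. A feature
#' no stump uses yields the zero curve. The curve's domain is the feature's
#' observed range in the full training table.
#'
#' @param ensemble a [StumpEnsemble-class].
#' @param feature feature name.
#' @return a [ScoreCurve-class].
#' @export
setMethod("scoreCurve", "StumpEnsemble", function(ensemble, feature) {
  if (!feature %in% colnames(ensemble@featureRanges))
    stop("unknown feature: ", feature)
  domain <- unname(ensemble@featureRanges[, feature])
  st <- .allStumps(ensemble)
  st <- st[st$feature == feature, , drop = FALSE]
  N <- nModels(ensemble)
  if (is.null(st) || !nrow(st))
    return(new("ScoreCurve", feature = feature, breaks = numeric(),
               values = 0, weights = numeric(), domain = domain))
  o <- order(st$theta)
  th <- st$theta[o]; vl <- st$vLeft[o]; vr <- st$vRight[o]; g <- st$gain[o]
  grp <- match(th, unique(th))
  breaks <- unique(th)
  # piece b (0..B) covers x in [breaks[b], breaks[b+1]); a stump fires
  # right iff its threshold <= the piece's lower edge
  cumR <- c(0, cumsum(rowsum(vr, grp)[, 1L]))
  cumL <- c(0, cumsum(rowsum(vl, grp)[, 1L]))
  totalL <- sum(vl)
  values <- (cumR + (totalL - cumL)) / N
  new("ScoreCurve", feature = feature, breaks = breaks,
      values = as.numeric(values),
      weights = as.numeric(rowsum(g, grp)[, 1L]), domain = domain)
})

#' Evaluate a score curve
#'
#' Right-continuous evaluation: at a breakpoint the `x >= theta` piece
#' applies, consistent with H(0) = 1.
#'
#' @param curve a [ScoreCurve-class].
#' @param x numeric vector.
#' @return numeric vector of curve values.
#' @export
scoreCurveValue <- function(curve, x) {
  if (!length(curve@breaks)) return(rep(curve@values, length(x)))
  curve@values[findInterval(x, curve@breaks) + 1L]
}

#' Evaluate a sigmoid shape function
#'
#' `f(x) = A / (1 + exp(k (x - t))) - m`, computed through `plogis` for
#' numerical stability at large `|k (x - t)|`.
#'
#' @param fit a [SigmoidFit-class] (or anything with slots A, t, k, m).
#' @param x numeric vector.
#' @return numeric vector of scores.
#' @export
sigmoidValue <- function(fit, x) {
  fit@A * plogis(-fit@k * (x - fit@t)) - fit@m
}

.newSigmoidFit <- function(A, t, k, m, rmse, domain, converged = TRUE) {
  f <- function(x) A * plogis(-k * (x - t)) - m
  new("SigmoidFit", A = A, t = t, k = k, m = m, rmse = rmse,
      domain = domain, outputRange = abs(f(domain[2]) - f(domain[1])),
      converged = converged)
}

#' Fit a four-parameter sigmoid to a score curve
#'
#' Least-squares fit of `A / (1 + exp(k (x - t))) - m` to the curve sampled
#' on `gridSize` uniform points over its domain (equal weights).
#' Initialisation: `A0` = curve range, `m0` = -(curve minimum), `t0` =
#' gain-weighted median of the stump thresholds, `k0` = +-1 with the sign
#' taken from the curve's overall trend. On failure the initials are
#' jittered for up to `restarts` further attempts; if none converges an
#' error reports the best achieved RMSE.
#'
#' A curve that is constant (range below `tol`) is returned directly as the
#' degenerate fit A = 0, m = -c.
#'
#' @param curve a [ScoreCurve-class] with a non-degenerate domain.
#' @param gridSize number of sampling points (default 200).
#' @param restarts additional jittered attempts (default 5).
#' @param tol numeric tolerance for a constant curve.
#' @return a [SigmoidFit-class].
#' @export
setMethod("fitSigmoid", "ScoreCurve",
  function(curve, gridSize = 200L, restarts = 5L, tol = 1e-12) {
    domain <- curve@domain
    if (!(domain[2] > domain[1]))
      stop("curve domain is degenerate for feature ", curve@feature)
    xs <- seq(domain[1], domain[2], length.out = gridSize)
    ys <- scoreCurveValue(curve, xs)
    rng <- max(ys) - min(ys)
    if (rng < tol)
      return(.newSigmoidFit(A = 0, t = mean(domain), k = 1, m = -ys[1],
                            rmse = 0, domain = domain))
    t0 <- .weightedMedian(curve@breaks, curve@weights)
    if (!is.finite(t0)) t0 <- mean(domain)
    k0 <- if (ys[gridSize] - ys[1] <= 0) 1 else -1
    k0 <- k0 * 4 / (domain[2] - domain[1])   # gentle initial slope
    start <- c(A = rng, t = t0, k = k0, m = -min(ys))
    dat <- data.frame(x = xs, y = ys)
    best <- NULL; bestRmse <- Inf
    for (i in 0:restarts) {
      st <- start
      if (i > 0) {
        st["A"] <- st["A"] * runif(1, 0.5, 2)
        st["t"] <- st["t"] + runif(1, -0.25, 0.25) * diff(domain)
        st["k"] <- st["k"] * runif(1, 0.3, 3)
        st["m"] <- st["m"] + runif(1, -0.5, 0.5) * rng
      }
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ A * plogis(-k * (x - t)) - m,
                          data = dat, start = as.list(st),
                          lower = c(A = 0, t = -Inf, k = -Inf, m = -Inf),
                          control = minpack.lm::nls.lm.control(
                            maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
        error = function(e) NULL)
      if (is.null(fit)) next
      p <- stats::coef(fit)
      rmse <- sqrt(mean(stats::resid(fit)^2))
      if (rmse < bestRmse) { best <- p; bestRmse <- rmse }
      if (rmse <= 1e-8) break
    }
    if (is.null(best)) {
      # Levenberg-Marquardt can hit singular gradients when the curve is a
      # single sharp step (A and k nearly unidentifiable); fall back to a
      # derivative-free simplex search on the same least-squares objective
      rmseOf <- function(p) {
        p["A"] <- abs(p["A"])
        sqrt(mean((p["A"] * plogis(-p["k"] * (xs - p["t"])) - p["m"] -
                     ys)^2))
      }
      opt <- stats::optim(start, rmseOf, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-14))
      best <- opt$par
      best["A"] <- abs(best["A"])
      bestRmse <- opt$value
      if (!is.finite(bestRmse))
        stop("sigmoid fit failed for feature ", curve@feature,
             " (best RMSE ", signif(bestRmse, 3), ")")
    }
    .newSigmoidFit(A = unname(best["A"]), t = unname(best["t"]),
                   k = unname(best["k"]), m = unname(best["m"]),
                   rmse = bestRmse, domain = domain)
  })

#' Build a sum-of-sigmoids model from a stump ensemble
#'
#' Takes the top `k` features of the gain ranking, computes each feature's
#' score curve and fits its sigmoid. The resulting model is self-contained:
#' prediction no longer involves the boosted models.
#'
#' @param ensemble a [StumpEnsemble-class].
#' @param k number of sigmoid terms.
#' @param ranking optional ranking data.frame (from [gainRanking()]);
#'   computed from the ensemble when omitted.
#' @return a [SumOfSigmoidsModel-class].
#' @export
buildSOSModel <- function(ensemble, k, ranking = gainRanking(ensemble)) {
  k <- as.integer(k)
  if (k < 1L || k > nrow(ranking))
    stop("k must be between 1 and the ranking length (", nrow(ranking), ")")
  feats <- ranking$feature[seq_len(k)]
  fits <- lapply(feats, function(f) {
    tryCatch(fitSigmoid(scoreCurve(ensemble, f)),
             error = function(e)
               stop("sigmoid fit failed for feature ", f, ": ",
                    conditionMessage(e), call. = FALSE))
  })
  new("SumOfSigmoidsModel", featureNames = as.character(feats),
      fits = fits,
      provenance = list(nModels = nModels(ensemble),
                        masterSeed = ensemble@masterSeed,
                        gains = setNames(ranking$gain[seq_len(k)], feats)))
}

#' @describeIn buildSOSModel feature names of the model
#' @param model a [SumOfSigmoidsModel-class].
#' @export
setMethod("modelFeatures", "SumOfSigmoidsModel",
          function(model) model@featureNames)

#' @describeIn buildSOSModel the list of per-feature [SigmoidFit-class]
#' @export
setMethod("sigmoidFits", "SumOfSigmoidsModel", function(model) {
  setNames(model@fits, model@featureNames)
})

#' @describeIn buildSOSModel output range |f(hi) - f(lo)| of a sigmoid fit
#' @param fit a [SigmoidFit-class].
#' @export
setMethod("outputRange", "SigmoidFit", function(fit) fit@outputRange)

#' Predict with a sum-of-sigmoids model
#'
#' Evaluates each sigmoid at its feature's value, sums the scores and
#' thresholds the sum with the Heaviside step: a nonnegative sum predicts
#' an event. Missing or non-finite feature values are an error; there is no
#' imputation.
#'
#' @param object a [SumOfSigmoidsModel-class].
#' @param newdata named numeric vector, patients x features matrix,
#'   data.frame, or feature-table SummarizedExperiment.
#' @param ... unused.
#' @return data.frame with one row per patient: per-feature score columns
#'   (`score.<feature>`), `sum`, and the binary `prediction`.
#' @export
setMethod("predict", "SumOfSigmoidsModel", function(object, newdata, ...) {
  if (is(newdata, "SummarizedExperiment")) newdata <- .featureMatrix(newdata)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, 1L, dimnames = list(NULL, names(newdata)))
  missing <- setdiff(object@featureNames, colnames(newdata))
  if (length(missing))
    stop("missing model feature(s): ", paste(missing, collapse = ", "))
  scores <- vapply(seq_along(object@featureNames), function(i) {
    xv <- newdata[, object@featureNames[i]]
    if (any(!is.finite(xv)))
      stop("non-finite value for feature ", object@featureNames[i])
    sigmoidValue(object@fits[[i]], xv)
  }, numeric(nrow(newdata)))
  scores <- matrix(scores, nrow = nrow(newdata))
  colnames(scores) <- paste0("score.", object@featureNames)
  total <- rowSums(scores)
  out <- data.frame(scores, check.names = FALSE)
  out$sum <- total
  out$prediction <- heaviside(total)
  out
})

#' Drop sigmoid terms with a small output range
#'
#' Removes every sigmoid whose output range over its domain is below
#' `minRange`; terms with a nearly flat score contribution barely affect
#' the summed score, so discarding them simplifies the model at little
#' cost. At least one sigmoid must survive.
#'
#' @param model a [SumOfSigmoidsModel-class].
#' @param minRange nonnegative threshold in score units.
#' @return the pruned [SumOfSigmoidsModel-class].
#' @export
setMethod("pruneSmallRange", "SumOfSigmoidsModel",
  function(model, minRange) {
    stopifnot(minRange >= 0)
    keep <- vapply(model@fits, outputRange, numeric(1)) >= minRange
    if (!any(keep))
      stop("pruning at minRange = ", minRange,
           " would remove every sigmoid")
    if (all(keep)) return(model)
    new("SumOfSigmoidsModel",
        featureNames = model@featureNames[keep],
        fits = model@fits[keep],
        provenance = c(model@provenance, list(prunedAt = minRange)))
  })

#' Test accuracy as a function of model size
#'
#' Builds the k-feature sum-of-sigmoids model for every k = 1..kMax and
#' evaluates its accuracy on the test set. Plotting accuracy against k and
#' choosing k from a stable part of the curve is the recommended way to
#' size the final model.
#'
#' @param ensemble a [StumpEnsemble-class].
#' @param test feature table with outcomes.
#' @param kMax largest model size; at most the ranking length.
#' @param ranking optional precomputed gain ranking.
#' @return data.frame with columns `k` and `accuracy`.
#' @export
accuracyVsK <- function(ensemble, test, kMax,
                        ranking = gainRanking(ensemble)) {
  kMax <- as.integer(kMax)
  if (kMax < 1L || kMax > nrow(ranking))
    stop("kMax must be between 1 and the ranking length")
  full <- buildSOSModel(ensemble, kMax, ranking = ranking)
  X <- .featureMatrix(test)
  y <- .outcomes(test)
  scores <- vapply(seq_len(kMax), function(i)
    sigmoidValue(full@fits[[i]], X[, full@featureNames[i]]),
    numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X))
  acc <- vapply(seq_len(kMax), function(k) {
    pred <- heaviside(rowSums(scores[, seq_len(k), drop = FALSE]))
    mean(pred == y)
  }, numeric(1))
  data.frame(k = seq_len(kMax), accuracy = acc)
}

#' Serialize / restore a sum-of-sigmoids model as JSON
#'
#' Full IEEE precision is written so that a round trip preserves
#' predictions exactly.
#'
#' @param model a [SumOfSigmoidsModel-class].
#' @param path JSON file path.
#' @return `readSOSModel` returns the restored model; `writeSOSModel`
#'   returns `path` invisibly.
#' @export
writeSOSModel <- function(model, path) {
  obj <- list(
    k = length(model@featureNames),
    features = lapply(seq_along(model@featureNames), function(i) {
      f <- model@fits[[i]]
      list(name = model@featureNames[i], A = f@A, t = f@t, k = f@k,
           m = f@m, domain = f@domain, range = f@outputRange,
           rmse = f@rmse)
    }),
    provenance = model@provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeSOSModel
#' @export
readSOSModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fits <- lapply(obj$features, function(f)
    .newSigmoidFit(A = f$A, t = f$t, k = f$k, m = f$m, rmse = f$rmse,
                   domain = as.numeric(unlist(f$domain))))
  feats <- vapply(obj$features, `[[`, character(1), "name")
  prov <- obj$provenance
  prov <- lapply(prov, function(p) if (is.list(p)) unlist(p) else p)
  new("SumOfSigmoidsModel", featureNames = feats, fits = fits,
      provenance = prov)
}

setMethod("show", "ScoreCurve", function(object) {
  cat(sprintf("ScoreCurve for %s: %d breakpoints on [%.3g, %.3g]\n",
              object@feature, length(object@breaks), object@domain[1],
              object@domain[2]))
  cat(sprintf("  piece values in [%.4g, %.4g]\n", min(object@values),
              max(object@values)))
})

setMethod("show", "SigmoidFit", function(object) {
  cat(sprintf(
    "SigmoidFit: f(x) = %.4g / (1 + exp(%.4g (x - %.4g))) - %.4g\n",
    object@A, object@k, object@t, object@m))
  cat(sprintf("  RMSE %.3g, output range %.4g on [%.3g, %.3g]\n",
              object@rmse, object@outputRange, object@domain[1],
              object@domain[2]))
})

setMethod("show", "SumOfSigmoidsModel", function(object) {
  cat(sprintf("SumOfSigmoidsModel with %d sigmoid terms:\n",
              length(object@featureNames)))
  for (i in seq_along(object@featureNames)) {
    f <- object@fits[[i]]
    cat(sprintf("  %-20s A=%.4g t=%.4g k=%.4g m=%.4g (range %.4g)\n",
                object@featureNames[i], f@A, f@t, f@k, f@m,
                f@outputRange))
  }
  cat("prediction: event iff sum of sigmoid scores >= 0\n")
})
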