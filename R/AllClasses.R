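#' @import methods
NULL

#' SegmentGeometry: the 17-segment bull's-eye layout
#'
#' Describes how a circular perfusion polar map is partitioned into the
#' standard AHA 17 segments: concentric rings at fixed fractions of the disc
#' radius, each ring cut into equal angular sectors.
#'
#' Rings are ordered from the outside in: basal (segments 1-6), mid (7-12),
#' apical (13-16) and apex (17). `boundaries` holds the increasing outer
#' radial edges of the rings as fractions of the disc radius, listed from the
#' apex outward (so the last entry is 1). `counts` and `offsets` are per-ring,
#' listed basal-first. Angles are measured in degrees from 12 o'clock,
#' counterclockwise; `offsets` rotates each ring's first sector boundary.
#'
#' @slot boundaries numeric, strictly increasing radial boundaries in (0, 1].
#' @slot counts integer, sectors per ring (basal first); must sum to 17.
#' @slot offsets numeric, angular offset in degrees per ring (basal first).
#'
#' @seealso [segmentGeometry()], [segmentMask()]
#' @export
setClass("SegmentGeometry",
  representation(boundaries = "numeric", counts = "integer",
                 offsets = "numeric"))

setValidity("SegmentGeometry", function(object) {
  b <- object@boundaries
  msg <- character()
  if (length(b) != length(object@counts) ||
      length(b) != length(object@offsets))
    msg <- c(msg, "boundaries, counts and offsets must have equal length")
  if (any(diff(b) <= 0) || b[1] <= 0 || abs(b[length(b)] - 1) > 1e-12)
    msg <- c(msg, "boundaries must increase strictly from >0 to 1")
  if (sum(object@counts) != 17L)
    msg <- c(msg, "segment counts must sum to 17")
  if (any(object@counts < 1L))
    msg <- c(msg, "each ring needs at least one segment")
  if (length(msg)) msg else TRUE
})

#' PolarMap: one perfusion polar map
#'
#' A dense raster of perfusion values (mL/g/min) over a disc, with a logical
#' mask marking in-disc pixels. One of three kinds: rest flow, stress flow,
#' or their pixelwise ratio (flow reserve).
#'
#' @slot grid numeric matrix of perfusion values; pixels outside the mask may
#'   be `NA`.
#' @slot mask logical matrix, `TRUE` inside the disc.
#' @slot kind one of `"REST"`, `"STRESS"`, `"RESERVE"`.
#' @slot center numeric length 2, (row, column) of the disc centre in pixel
#'   coordinates.
#' @slot radius disc radius in pixels.
#'
#' @seealso [polarMap()], [segmentStatistics()]
#' @export
setClass("PolarMap",
  representation(grid = "matrix", mask = "matrix", kind = "character",
                 center = "numeric", radius = "numeric"))

setValidity("PolarMap", function(object) {
  msg <- character()
  if (!object@kind %in% c("REST", "STRESS", "RESERVE"))
    msg <- c(msg, "kind must be REST, STRESS or RESERVE")
  if (nrow(object@grid) < 32L || ncol(object@grid) < 32L)
    msg <- c(msg, "grid must be at least 32 x 32")
  if (!identical(dim(object@grid), dim(object@mask)))
    msg <- c(msg, "grid and mask dimensions differ")
  inside <- object@grid[object@mask]
  if (anyNA(inside) || any(!is.finite(inside)))
    msg <- c(msg, "all in-disc values must be finite")
  else if (any(inside < 0))
    msg <- c(msg, "perfusion values must be nonnegative")
  idx <- which(object@mask, arr.ind = TRUE)
  if (nrow(idx)) {
    rn <- sqrt((idx[, 1] - object@center[1])^2 +
               (idx[, 2] - object@center[2])^2) / object@radius
    if (any(rn > 1 + 1e-9))
      msg <- c(msg, "mask pixels must lie within the disc radius")
  }
  if (length(msg)) msg else TRUE
})

#' SplitReport: diagnostics of a train/test split
#'
#' Records the per-feature Kruskal-Wallis comparison of the train and test
#' marginals (raw and FDR-adjusted p-values), the outcome prevalence ratios
#' r1 (event-free) and r2 (event) between the two sets, and the resulting
#' pass/fail decision.
#'
#' @slot pValues,pAdjusted named numeric, per-feature raw and
#'   Benjamini-Hochberg adjusted Kruskal p-values.
#' @slot r1,r2 prevalence ratios train/test for the negative and positive
#'   class.
#' @slot flagged names of features whose adjusted p-value fell at or below
#'   the significance level.
#' @slot passed logical pass/fail.
#' @slot alpha significance level used.
#' @slot ratioBound upper ratio bound b; ratios must satisfy 1/b < r < b.
#' @slot seed seed that produced the split (NA when validated standalone).
#' @slot nTrain,nTest set sizes.
#' @export
setClass("SplitReport",
  representation(pValues = "numeric", pAdjusted = "numeric",
                 r1 = "numeric", r2 = "numeric", flagged = "character",
                 passed = "logical", alpha = "numeric",
                 ratioBound = "numeric", seed = "integer",
                 nTrain = "integer", nTest = "integer"))

setValidity("SplitReport", function(object) {
  if (any(object@pAdjusted < object@pValues - 1e-12))
    return("adjusted p-values must not be smaller than raw p-values")
  if (length(object@r1) && (object@r1 <= 0 || object@r2 <= 0))
    return("prevalence ratios must be positive")
  TRUE
})

#' StratifiedSet: an undersampled training subset
#'
#' The result of randomly discarding majority-class (event-free) patients to
#' reach a target positive fraction. All positives are always retained.
#'
#' @slot indices integer column indices into the source set, sorted.
#' @slot positiveFraction achieved fraction of positives.
#' @slot seed seed used for the draw.
#' @export
setClass("StratifiedSet",
  representation(indices = "integer", positiveFraction = "numeric",
                 seed = "integer"))

#' EnsembleConfig: training configuration for a stump ensemble
#'
#' @slot nModels number of independently stratified boosted models.
#' @slot nrounds boosting rounds per model (each round adds one stump).
#' @slot eta learning rate in (0, 1].
#' @slot subsample,colsampleBytree optional row/column subsampling in (0, 1].
#' @slot targetPosFraction positive fraction targeted by the per-model
#'   stratification undersampling.
#' @export
setClass("EnsembleConfig",
  representation(nModels = "integer", nrounds = "integer", eta = "numeric",
                 subsample = "numeric", colsampleBytree = "numeric",
                 targetPosFraction = "numeric"))

setValidity("EnsembleConfig", function(object) {
  msg <- character()
  if (object@nModels < 1L) msg <- c(msg, "nModels must be >= 1")
  if (object@nrounds < 1L) msg <- c(msg, "nrounds must be >= 1")
  if (object@eta <= 0 || object@eta > 1)
    msg <- c(msg, "eta must be in (0, 1]")
  if (object@targetPosFraction <= 0 || object@targetPosFraction >= 1)
    msg <- c(msg, "targetPosFraction must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' StumpEnsemble: N depth-one boosted models as explicit stump lists
#'
#' Each member model is a gradient-boosted tree model of maximum depth one,
#' reduced to its list of stumps: threshold tests
#' "is feature x >= theta? add vRight, else add vLeft" plus a per-model bias.
#' The ensemble also records the observed range of every feature in the full
#' training table, which later bounds the score-curve domains.
#'
#' @slot models list; each element has `bias` (numeric), `seed` (integer) and
#'   `stumps`, a data.frame with columns `feature`, `theta`, `vLeft`,
#'   `vRight`, `gain`.
#' @slot config the [EnsembleConfig-class] used.
#' @slot featureRanges 2 x p numeric matrix (rows `lo`, `hi`) of training
#'   feature ranges.
#' @slot masterSeed the single integer all per-model seeds derive from.
#' @export
setClass("StumpEnsemble",
  representation(models = "list", config = "EnsembleConfig",
                 featureRanges = "matrix", masterSeed = "integer"))

setValidity("StumpEnsemble", function(object) {
  if (length(object@models) < 1L)
    return("ensemble must contain at least one model")
  ok <- vapply(object@models, function(m) {
    is.list(m) && is.data.frame(m$stumps) &&
      all(c("feature", "theta", "vLeft", "vRight", "gain") %in%
            names(m$stumps))
  }, logical(1))
  if (!all(ok)) return("malformed model entry")
  TRUE
})

#' ScoreCurve: a feature's average additive contribution
#'
#' Piecewise-constant curve giving, as a function of one input variable, the
#' average contribution of that variable's stumps across the ensemble
#' (summed per model, averaged over the N models). Right-continuous at
#' breakpoints: at x = theta the stump fires its x >= theta leaf, matching
#' H(0) = 1.
#'
#' @slot feature feature name.
#' @slot breaks sorted distinct thresholds.
#' @slot values piece values, `length(breaks) + 1`; `values[i]` applies on
#'   `[breaks[i-1], breaks[i])`.
#' @slot weights summed gain attached to each breakpoint (used to initialise
#'   sigmoid fits).
#' @slot domain numeric length 2, the feature's observed training range.
#' @export
setClass("ScoreCurve",
  representation(feature = "character", breaks = "numeric",
                 values = "numeric", weights = "numeric",
                 domain = "numeric"))

setValidity("ScoreCurve", function(object) {
  msg <- character()
  if (length(object@values) != length(object@breaks) + 1L)
    msg <- c(msg, "need exactly one more piece value than breakpoints")
  if (is.unsorted(object@breaks, strictly = TRUE))
    msg <- c(msg, "breakpoints must be strictly increasing")
  if (length(object@domain) != 2L || object@domain[2] < object@domain[1])
    msg <- c(msg, "domain must be an ordered pair")
  if (length(msg)) msg else TRUE
})

#' SigmoidFit: four-parameter sigmoid approximation of a score curve
#'
#' The shape function f(x) = A / (1 + exp(k (x - t))) - m. With k > 0 the
#' function decreases in x (here: higher flow, lower risk score); a single
#' sigmoid is monotone by construction.
#'
#' @slot A amplitude (score units), nonnegative.
#' @slot t location (feature units).
#' @slot k steepness (1/feature units); sign sets the direction.
#' @slot m offset (score units).
#' @slot rmse root-mean-square error of the fit on its sampling grid.
#' @slot domain the score curve's domain the fit was performed on.
#' @slot outputRange |f(hi) - f(lo)| over the domain.
#' @slot converged logical, whether the optimiser reported convergence.
#' @export
setClass("SigmoidFit",
  representation(A = "numeric", t = "numeric", k = "numeric", m = "numeric",
                 rmse = "numeric", domain = "numeric",
                 outputRange = "numeric", converged = "logical"))

setValidity("SigmoidFit", function(object) {
  if (object@A < 0) return("amplitude A must be nonnegative")
  if (!is.finite(object@rmse)) return("rmse must be finite")
  TRUE
})

#' SumOfSigmoidsModel: the interpretable binary predictor
#'
#' An ordered set of per-feature sigmoid shape functions. The prediction for
#' a patient is the Heaviside step of the sum of the sigmoid scores: 1 (an
#' event is predicted) when the sum is >= 0, else 0. The model is constructed
#' from a stump ensemble by curve fitting, not trained; once built it is
#' independent of the ensemble.
#'
#' @slot featureNames distinct feature names, in selection order.
#' @slot fits list of [SigmoidFit-class], parallel to `featureNames`.
#' @slot provenance list describing how the model was built (ensemble size,
#'   master seed, gain ranking used).
#' @export
setClass("SumOfSigmoidsModel",
  representation(featureNames = "character", fits = "list",
                 provenance = "list"))

setValidity("SumOfSigmoidsModel", function(object) {
  if (length(object@featureNames) < 1L)
    return("model needs at least one sigmoid term")
  if (anyDuplicated(object@featureNames))
    return("feature names must be distinct")
  if (length(object@fits) != length(object@featureNames))
    return("one fit per feature required")
  if (!all(vapply(object@fits, is, logical(1), "SigmoidFit")))
    return("fits must be SigmoidFit objects")
  TRUE
})

#' ConfusionReport: confusion counts and derived classification metrics
#'
#' @slot counts named integer (TN, FP, FN, TP).
#' @slot byClass 2 x 3 matrix (rows `negative`, `positive`; columns
#'   `precision`, `recall`, `f1`), unrounded.
#' @slot accuracy overall accuracy.
#' @slot weighted named numeric (precision, recall, f1), support-weighted
#'   class averages.
#' @slot supports named integer class supports (negative = TN + FP,
#'   positive = FN + TP).
#' @slot degenerate names of metrics whose denominator was zero (reported
#'   as 0).
#' @export
setClass("ConfusionReport",
  representation(counts = "integer", byClass = "matrix",
                 accuracy = "numeric", weighted = "numeric",
                 supports = "integer", degenerate = "character"))

setValidity("ConfusionReport", function(object) {
  cnt <- object@counts
  if (!identical(names(cnt), c("TN", "FP", "FN", "TP")))
    return("counts must be named TN, FP, FN, TP")
  if (any(cnt < 0L)) return("counts must be nonnegative")
  if (sum(cnt) == 0L) return("total count must be positive")
  if (abs(object@accuracy - (cnt["TN"] + cnt["TP"]) / sum(cnt)) > 1e-12)
    return("accuracy inconsistent with counts")
  TRUE
})

#' GroundTruthSOS: a known generating sum-of-sigmoids model
#'
#' Ground truth for recovery experiments: labels are the Heaviside step of a
#' known sum of sigmoids, with a small label-flip rate epsilon.
#'
#' @slot model the generating [SumOfSigmoidsModel-class].
#' @slot flipRate label noise epsilon in [0, 0.5).
#' @export
setClass("GroundTruthSOS",
  representation(model = "SumOfSigmoidsModel", flipRate = "numeric"))

setValidity("GroundTruthSOS", function(object) {
  if (object@flipRate < 0 || object@flipRate >= 0.5)
    return("flipRate must be in [0, 0.5)")
  TRUE
})

#' SyntheticCohortConfig: parameters of the synthetic perfusion cohort
#'
#' Defines the simulated study conditions: cohort size, target event
#' prevalence (default 0.126, i.e. roughly 102 events per 809 patients),
#' segment-level mean flows for the rest (0.9 mL/g/min) and stress
#' (2.2 mL/g/min) maps, pixel noise, between-patient variability, and a
#' causal specification linking a few segment statistics to the event
#' log-odds through a logistic model whose intercept is solved to hit the
#' target prevalence. The reserve map is the pixelwise stress/rest ratio.
#'
#' @slot nPatients cohort size.
#' @slot prevalence target event rate in (0, 1).
#' @slot restMean,stressMean population mean segment flow (mL/g/min).
#' @slot restBetweenSD,stressBetweenSD between-patient SD of segment mean
#'   flows (mL/g/min).
#' @slot pixelNoiseSD within-segment additive pixel noise SD (mL/g/min).
#' @slot causal data.frame with columns `feature` (canonical feature name)
#'   and `effect` (log-odds change per SD of the statistic; negative means
#'   higher values protect).
#' @slot rasterSize raster side length H = W (>= 32).
#' @export
setClass("SyntheticCohortConfig",
  representation(nPatients = "integer", prevalence = "numeric",
                 restMean = "numeric", stressMean = "numeric",
                 restBetweenSD = "numeric", stressBetweenSD = "numeric",
                 pixelNoiseSD = "numeric", causal = "data.frame",
                 rasterSize = "integer"))

setValidity("SyntheticCohortConfig", function(object) {
  msg <- character()
  if (object@prevalence <= 0 || object@prevalence >= 1)
    msg <- c(msg, "prevalence must be in (0, 1)")
  if (object@restMean <= 0 || object@stressMean <= 0)
    msg <- c(msg, "mean flows must be positive")
  if (object@rasterSize < 32L)
    msg <- c(msg, "rasterSize must be >= 32")
  if (nrow(object@causal) &&
      !all(c("feature", "effect") %in% names(object@causal)))
    msg <- c(msg, "causal needs columns feature, effect")
  if (nrow(object@causal) && any(!is.finite(object@causal$effect)))
    msg <- c(msg, "causal effects must be finite")
  if (length(msg)) msg else TRUE
})
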