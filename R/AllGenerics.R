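#' @include AllClasses.R
NULL

#' @export
setGeneric("segmentMask", function(geometry, map, segment)
  standardGeneric("segmentMask"))

#' @export
setGeneric("segmentStatistics", function(map, geometry, ...)
  standardGeneric("segmentStatistics"))

#' @export
setGeneric("gainRanking", function(ensemble, ...)
  standardGeneric("gainRanking"))

#' @export
setGeneric("ensembleMargin", function(ensemble, x, ...)
  standardGeneric("ensembleMargin"))

#' @export
setGeneric("scoreCurve", function(ensemble, feature, ...)
  standardGeneric("scoreCurve"))

#' @export
setGeneric("fitSigmoid", function(curve, ...)
  standardGeneric("fitSigmoid"))

#' @export
setGeneric("pruneSmallRange", function(model, minRange)
  standardGeneric("pruneSmallRange"))

#' @export
setGeneric("weightedAverages", function(report)
  standardGeneric("weightedAverages"))

#' @export
setGeneric("accuracy", function(report) standardGeneric("accuracy"))

#' @export
setGeneric("classMetrics", function(report) standardGeneric("classMetrics"))

#' @export
setGeneric("nModels", function(ensemble) standardGeneric("nModels"))

#' @export
setGeneric("modelFeatures", function(model) standardGeneric("modelFeatures"))

#' @export
setGeneric("sigmoidFits", function(model) standardGeneric("sigmoidFits"))

#' @export
setGeneric("outputRange", function(fit) standardGeneric("outputRange"))

#' @export
setGeneric("mapKind", function(map) standardGeneric("mapKind"))

#' @export
setGeneric("generateCohort", function(config, seed, ...)
  standardGeneric("generateCohort"))

#' @export
setGeneric("sampleFromGroundTruth", function(gt, n, seed, ...)
  standardGeneric("sampleFromGroundTruth"))
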