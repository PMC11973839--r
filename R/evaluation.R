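#' Confusion counts
#'
#' @param truth,predictions binary 0/1 vectors of equal length.
#' @return named integer vector (TN, FP, FN, TP).
#' @examples
#' confusionCounts(c(0, 1, 0, 1), c(0, 1, 0, 1))
#' @export
confusionCounts <- function(truth, predictions) {
  if (length(truth) != length(predictions))
    stop("truth and predictions must have equal length")
  .assertBinary(truth, "truth")
  .assertBinary(predictions, "predictions")
  c(TN = sum(truth == 0 & predictions == 0),
    FP = sum(truth == 0 & predictions == 1),
    FN = sum(truth == 1 & predictions == 0),
    TP = sum(truth == 1 & predictions == 1))
}

.safeRate <- function(num, den, label, flags) {
  if (den == 0) list(value = 0, flags = c(flags, label))
  else list(value = num / den, flags = flags)
}

#' Classification metrics from confusion counts
#'
#' Computes per-class precision, recall and f1 (the positive class is
#' "patients with an event"), the overall accuracy, and support-weighted
#' averages of the per-class metrics. Internal values are never rounded;
#' the `show` method displays two decimals (half-up), matching the usual
#' reporting convention. Rates with a zero denominator are reported as 0
#' and flagged in `@degenerate`.
#'
#' @param TN,FP,FN,TP nonnegative counts, or a single named vector from
#'   [confusionCounts()] passed as `TN`.
#' @return a [ConfusionReport-class].
#' @examples
#' rep <- metricsFromCounts(196, 38, 7, 29)
#' accuracy(rep)
#' @export
metricsFromCounts <- function(TN, FP = NULL, FN = NULL, TP = NULL) {
  if (is.null(FP) && length(TN) == 4L) {
    cnt <- TN
    TN <- cnt[["TN"]]; FP <- cnt[["FP"]]; FN <- cnt[["FN"]]; TP <- cnt[["TP"]]
  }
  counts <- as.integer(c(TN, FP, FN, TP))
  if (any(counts < 0L)) stop("counts must be nonnegative")
  if (sum(counts) == 0L) stop("total count must be positive")
  names(counts) <- c("TN", "FP", "FN", "TP")
  flags <- character()
  pp <- .safeRate(TP, TP + FP, "precision_positive", flags)
  flags <- pp$flags
  rp <- .safeRate(TP, TP + FN, "recall_positive", flags)
  flags <- rp$flags
  pn <- .safeRate(TN, TN + FN, "precision_negative", flags)
  flags <- pn$flags
  rn <- .safeRate(TN, TN + FP, "recall_negative", flags)
  flags <- rn$flags
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  byClass <- rbind(
    negative = c(precision = pn$value, recall = rn$value,
                 f1 = f1(pn$value, rn$value)),
    positive = c(precision = pp$value, recall = rp$value,
                 f1 = f1(pp$value, rp$value)))
  supports <- c(negative = TN + FP, positive = FN + TP)
  acc <- (TN + TP) / sum(counts)
  if (all(supports > 0)) {
    w <- supports / sum(supports)
    weighted <- c(precision = sum(w * byClass[, "precision"]),
                  recall = sum(w * byClass[, "recall"]),
                  f1 = sum(w * byClass[, "f1"]))
  } else {
    present <- which(supports > 0)
    weighted <- byClass[present, ]
    flags <- c(flags, "weighted_single_class")
  }
  new("ConfusionReport", counts = counts, byClass = byClass,
      accuracy = acc, weighted = weighted,
      supports = setNames(as.integer(supports), names(supports)),
      degenerate = flags)
}

#' @describeIn metricsFromCounts overall accuracy
#' @param report a [ConfusionReport-class].
#' @export
setMethod("accuracy", "ConfusionReport", function(report) report@accuracy)

#' @describeIn metricsFromCounts 2 x 3 per-class precision/recall/f1
#' @export
setMethod("classMetrics", "ConfusionReport",
          function(report) report@byClass)

#' Support-weighted average metrics
#'
#' Weights each class's precision, recall and f1 by its support. The
#' weighted recall equals the accuracy identically. With an empty class the
#' other class's metrics are returned (flagged in the report).
#'
#' @param report a [ConfusionReport-class].
#' @return named numeric (precision, recall, f1).
#' @export
setMethod("weightedAverages", "ConfusionReport",
          function(report) report@weighted)

setMethod("show", "ConfusionReport", function(object) {
  cnt <- object@counts
  cat(sprintf("ConfusionReport (n = %d): TN=%d FP=%d FN=%d TP=%d\n",
              sum(cnt), cnt["TN"], cnt["FP"], cnt["FN"], cnt["TP"]))
  m <- .round2(object@byClass)
  cat(sprintf("  %-28s %9s %6s %8s\n", "", "Precision", "Recall",
              "f1-score"))
  cat(sprintf("  %-28s %9.2f %6.2f %8.2f\n", "Patients without an event",
              m["negative", 1], m["negative", 2], m["negative", 3]))
  cat(sprintf("  %-28s %9.2f %6.2f %8.2f\n", "Patients with an event",
              m["positive", 1], m["positive", 2], m["positive", 3]))
  cat(sprintf("  %-28s %9s %6s %8.2f\n", "Accuracy", "", "",
              .round2(object@accuracy)))
  w <- .round2(object@weighted)
  cat(sprintf("  %-28s %9.2f %6.2f %8.2f\n", "Weighted averages", w[1],
              w[2], w[3]))
  if (length(object@degenerate))
    cat("  degenerate rates reported as 0:",
        paste(object@degenerate, collapse = ", "), "\n")
})

#' L1-regularised logistic baseline
#'
#' Standard comparison model: lasso-penalised logistic regression on all
#' features of a stratified training set, thresholded at probability 0.5.
#'
#' @param train stratified training feature table (with `MACE`).
#' @param test test feature table (with `MACE`).
#' @param lambda penalty strength; when `NULL`, chosen by 5-fold
#'   cross-validation (`lambda.min`).
#' @param seed seed for the cross-validation folds.
#' @return list with `predictions` (0/1 vector), `report`
#'   (a [ConfusionReport-class]) and the fitted glmnet `model`.
#' @export
baselineL1Logistic <- function(train, test, lambda = NULL, seed = 1L) {
  X <- .featureMatrix(train)
  y <- .outcomes(train)
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  if (is.null(lambda)) {
    set.seed(as.integer(seed))
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                            nfolds = 5)
    lambda <- cv$lambda.min
  }
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = lambda)
  p <- as.numeric(stats::predict(fit, .featureMatrix(test),
                                 type = "response"))
  pred <- as.numeric(p >= 0.5)
  list(predictions = pred,
       report = metricsFromCounts(confusionCounts(.outcomes(test), pred)),
       model = fit)
}

#' Side-by-side model comparison table
#'
#' @param reports named list of [ConfusionReport-class] objects; column
#'   order follows the input order.
#' @return data.frame with rows Accuracy, TN, FP, FN, TP and one column
#'   per method.
#' @export
comparisonTable <- function(reports) {
  stopifnot(length(reports) >= 1L)
  cols <- lapply(reports, function(r)
    c(Accuracy = unname(r@accuracy), r@counts))
  out <- as.data.frame(cols, check.names = FALSE)
  colnames(out) <- names(reports)
  out
}

#' Reference confusion counts from the clinical PET MPI cohort
#'
#' Test-set confusion counts (270 patients, 36 events) reported for the
#' clinical 13N-ammonia PET myocardial perfusion cohort on which the
#' sum-of-sigmoids approach was developed: a convolutional neural network
#' on reserve maps, a depth-six boosted-tree model and a lasso-logistic
#' model on all 663 features, and the four-term sum-of-sigmoids model.
#' Included so reports and comparison tables can be reproduced and checked
#' without access to the clinical data.
#'
#' @return data.frame with columns `method`, `TN`, `FP`, `FN`, `TP`.
#' @export
referenceCohortCounts <- function() {
  data.frame(
    method = c("cnn", "boosted_tree", "lasso_logistic", "sum_of_sigmoids"),
    TN = c(202L, 191L, 192L, 196L),
    FP = c(32L, 43L, 42L, 38L),
    FN = c(11L, 4L, 5L, 7L),
    TP = c(25L, 32L, 31L, 29L))
}

#' Per-case visualization data for a sum-of-sigmoids prediction
#'
#' For each model feature, returns the sampled sigmoid curve, the case's
#' own (x, score) point, the AHA segment the feature refers to, and (when
#' a polar map is supplied) the segment's pixel mask for overlay
#' highlighting.
#'
#' @param model a [SumOfSigmoidsModel-class].
#' @param x named feature vector of the case.
#' @param geometry a [SegmentGeometry-class].
#' @param maps optional named list of [PolarMap-class] objects
#'   (`REST`/`STRESS`/`RESERVE`) used to compute overlay masks.
#' @param nCurve points per sampled curve.
#' @return list with one element per feature: `feature`, `segment`,
#'   `curve` (data.frame x, score), `point` (x, score), `mask` (logical
#'   matrix or NULL); plus attribute `sum`, the summed case score.
#' @export
caseScoreFigureData <- function(model, x, geometry = segmentGeometry(),
                                maps = NULL, nCurve = 200L) {
  pred <- predict(model, x)
  panels <- lapply(seq_along(model@featureNames), function(i) {
    f <- model@featureNames[i]
    fit <- model@fits[[i]]
    seg <- as.integer(sub(".*_S([0-9]+)_.*", "\\1", f))
    kind <- sub("_.*", "", f)
    xs <- seq(fit@domain[1], fit@domain[2], length.out = nCurve)
    mask <- if (!is.null(maps) && kind %in% names(maps))
      segmentMask(geometry, maps[[kind]], seg) else NULL
    list(feature = f, segment = seg,
         curve = data.frame(x = xs, score = sigmoidValue(fit, xs)),
         point = c(x = unname(x[f]),
                   score = pred[[paste0("score.", f)]][1]),
         mask = mask)
  })
  attr(panels, "sum") <- pred$sum[1]
  panels
}
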