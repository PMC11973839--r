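#' @importFrom stats kruskal.test p.adjust
NULL

# two-group Kruskal-Wallis p-value; a feature constant across both sets
# carries no evidence of a distribution shift, so p is defined as 1
.kruskalP <- function(a, b) {
  v <- c(a, b)
  if (length(unique(v)) < 2L) return(1)
  g <- factor(rep(c("train", "test"), c(length(a), length(b))))
  kruskal.test(v, g)$p.value
}

#' Validate a train/test split
#'
#' Checks that (i) no feature's marginal distribution differs between the
#' train and test set according to a Benjamini-Hochberg FDR-corrected
#' Kruskal-Wallis test at level `alpha`, and (ii) the outcome prevalence
#' ratios r1 (event-free) and r2 (event) between train and test lie strictly
#' inside `(1/ratioBound, ratioBound)`.
#'
#' Features constant across both sets get p = 1 and are reported via a
#' message.
#'
#' @param train,test feature tables (SummarizedExperiments with a `MACE`
#'   outcome) as produced by [makeFeatureTable()].
#' @param alpha significance level for the adjusted p-values (default .05).
#' @param ratioBound prevalence ratio bound b, requiring 1/b < r < b
#'   (default 1.1).
#' @return a [SplitReport-class].
#' @export
validateSplit <- function(train, test, alpha = 0.05, ratioBound = 1.1) {
  Xtr <- .featureMatrix(train); Xte <- .featureMatrix(test)
  ytr <- .outcomes(train);      yte <- .outcomes(test)
  if (!nrow(Xtr) || !nrow(Xte)) stop("both sets must be non-empty")
  if (length(unique(ytr)) < 2L || length(unique(yte)) < 2L)
    stop("both outcome classes must be present in each set")
  stopifnot(identical(colnames(Xtr), colnames(Xte)))
  p <- vapply(seq_len(ncol(Xtr)),
              function(j) .kruskalP(Xtr[, j], Xte[, j]), numeric(1))
  names(p) <- colnames(Xtr)
  constant <- names(p)[vapply(seq_len(ncol(Xtr)), function(j)
    length(unique(c(Xtr[, j], Xte[, j]))) < 2L, logical(1))]
  if (length(constant))
    message("constant feature(s) across both sets (p set to 1): ",
            paste(utils::head(constant, 5), collapse = ", "))
  padj <- p.adjust(p, method = "BH")
  r1 <- mean(ytr == 0) / mean(yte == 0)
  r2 <- mean(ytr == 1) / mean(yte == 1)
  flagged <- names(padj)[padj <= alpha]
  ratiosOk <- all(c(r1, r2) > 1 / ratioBound & c(r1, r2) < ratioBound)
  new("SplitReport", pValues = p, pAdjusted = padj, r1 = r1, r2 = r2,
      flagged = flagged, passed = length(flagged) == 0L && ratiosOk,
      alpha = alpha, ratioBound = ratioBound, seed = NA_integer_,
      nTrain = nrow(Xtr), nTest = nrow(Xte))
}

#' Train/test sizes under the rounding rule
#'
#' The test set takes `round(testFraction * n)` patients and the training
#' set the remainder, so a 1079-patient cohort at 3:1 gives 809/270 and a
#' 4-patient cohort gives 3/1.
#'
#' @param n cohort size.
#' @param testFraction test proportion in (0, 1).
#' @return named integer vector (train, test).
#' @export
splitSizes <- function(n, testFraction = 0.25) {
  stopifnot(testFraction > 0, testFraction < 1, n >= 2)
  nTest <- as.integer(round(testFraction * n))
  c(train = as.integer(n) - nTest, test = nTest)
}

#' Random validated train/test split
#'
#' Randomly partitions the cohort, taking `round(testFraction * n)` patients
#' as the test set (a 1079-patient cohort at 3:1 yields 809 train / 270
#' test), then validates the split with [validateSplit()]. If validation
#' fails the split is redrawn with seed + 1, up to `maxRedraws` attempts.
#'
#' @param se feature table with outcomes.
#' @param testFraction test proportion in (0, 1); default 0.25 (3:1).
#' @param seed integer seed for the first draw.
#' @param maxRedraws maximum number of attempts (default 100).
#' @param alpha,ratioBound passed to [validateSplit()].
#' @return list with elements `train`, `test` (SummarizedExperiments) and
#'   `report` (a passing [SplitReport-class]).
#' @export
splitTrainTest <- function(se, testFraction = 0.25, seed = 1L,
                           maxRedraws = 100L, alpha = 0.05,
                           ratioBound = 1.1) {
  stopifnot(testFraction > 0, testFraction < 1)
  y <- .outcomes(se)
  if (min(table(factor(y, levels = 0:1))) < 2L)
    stop("need at least 2 patients per outcome class")
  n <- ncol(se)
  nTest <- splitSizes(n, testFraction)[["test"]]
  if (nTest < 1L || nTest >= n) stop("degenerate test-set size")
  report <- NULL
  for (attempt in seq_len(maxRedraws)) {
    s <- as.integer(seed) + attempt - 1L
    set.seed(s)
    testIdx <- sort(sample.int(n, nTest))
    train <- se[, -testIdx]; test <- se[, testIdx]
    if (length(unique(.outcomes(train))) < 2L ||
        length(unique(.outcomes(test))) < 2L) next
    report <- validateSplit(train, test, alpha = alpha,
                            ratioBound = ratioBound)
    report@seed <- s
    if (report@passed)
      return(list(train = train, test = test, report = report))
  }
  if (is.null(report))
    stop("no draw produced both outcome classes in both sets within ",
         maxRedraws, " attempts")
  stop("no validated split found in ", maxRedraws, " attempts; ",
       "last report: ", length(report@flagged), " flagged feature(s), ",
       sprintf("r1 = %.3f, r2 = %.3f", report@r1, report@r2))
}

#' Stratify a training set by undersampling the majority class
#'
#' Keeps every positive (event) patient and a random subset of
#' `round(nPos * (1 - p) / p)` negatives, so the positive fraction is as
#' close to the target `p` as integer counts allow (102 positives at
#' p = 0.4 keep 153 negatives). If the positive fraction already meets or
#' exceeds the target, all patients are kept with a warning.
#'
#' @param se feature table with outcomes.
#' @param targetPosFraction target positive fraction (default 0.4, i.e.
#'   roughly balanced but keeping more of the data).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a [StratifiedSet-class]; use [stratifiedSubset()] to materialise
#'   the subset.
#' @export
stratifyUndersample <- function(se, targetPosFraction = 0.4, seed = 1L) {
  p <- targetPosFraction
  stopifnot(p > 0, p < 1)
  y <- .outcomes(se)
  pos <- which(y == 1L); neg <- which(y == 0L)
  if (!length(pos)) stop("at least one positive case is required")
  if (mean(y) >= p) {
    warning("positive fraction ", signif(mean(y), 3),
            " already at or above target ", p, "; keeping all patients")
    return(new("StratifiedSet", indices = seq_along(y),
               positiveFraction = mean(y), seed = as.integer(seed)))
  }
  nNeg <- min(length(neg), round(length(pos) * (1 - p) / p))
  set.seed(as.integer(seed))
  keep <- sort(c(pos, sample(neg, nNeg)))
  new("StratifiedSet", indices = keep,
      positiveFraction = length(pos) / length(keep),
      seed = as.integer(seed))
}

#' Materialise a stratified subset
#'
#' @param se the source feature table.
#' @param strat a [StratifiedSet-class] from [stratifyUndersample()].
#' @return the subset SummarizedExperiment.
#' @export
stratifiedSubset <- function(se, strat) se[, strat@indices]

setMethod("show", "SplitReport", function(object) {
  cat(sprintf("SplitReport: %d train / %d test - %s\n", object@nTrain,
              object@nTest, if (object@passed) "PASS" else "FAIL"))
  cat(sprintf("  min adjusted Kruskal p = %.3g (alpha = %.2f), %d flagged\n",
              min(object@pAdjusted), object@alpha, length(object@flagged)))
  cat(sprintf("  prevalence ratios r1 = %.3f, r2 = %.3f (bound %.2f)\n",
              object@r1, object@r2, object@ratioBound))
})

setMethod("show", "StratifiedSet", function(object) {
  cat(sprintf(
    "StratifiedSet: %d patients, positive fraction %.3f (seed %d)\n",
    length(object@indices), object@positiveFraction, object@seed))
})
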