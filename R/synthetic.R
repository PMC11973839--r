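#' @importFrom stats rnorm rbinom qlogis uniroot
NULL

#' Configure a synthetic perfusion cohort
#'
#' Defaults emulate the shape of a clinical PET MPI MACE cohort: target
#' event prevalence 0.126 (about 102 events per 809 patients), mean rest
#' flow 0.9 mL/g/min and mean stress flow 2.2 mL/g/min, and a monotone
#' decreasing link from low stress/reserve segment flows to event risk
#' through four causal segment statistics with effect -1 on the log-odds
#' scale per SD.
#'
#' @param nPatients cohort size.
#' @param prevalence target event rate.
#' @param restMean,stressMean population mean segment flows (mL/g/min).
#' @param restBetweenSD,stressBetweenSD between-patient SD of the segment
#'   mean flows.
#' @param pixelNoiseSD additive within-segment pixel noise SD.
#' @param causal data.frame (`feature`, `effect`); effects act on the
#'   standardized segment statistics, negative = protective.
#' @param rasterSize raster side length (>= 32); 64 is the "small" preset
#'   used throughout the tests, 128 the full-size default for fixtures.
#' @return a [SyntheticCohortConfig-class].
#' @export
syntheticCohortConfig <- function(nPatients = 500L, prevalence = 0.126,
                                  restMean = 0.9, stressMean = 2.2,
                                  restBetweenSD = 0.15,
                                  stressBetweenSD = 0.45,
                                  pixelNoiseSD = 0.15,
                                  causal = defaultCausalSpec(),
                                  rasterSize = 64L) {
  new("SyntheticCohortConfig", nPatients = as.integer(nPatients),
      prevalence = prevalence, restMean = restMean,
      stressMean = stressMean, restBetweenSD = restBetweenSD,
      stressBetweenSD = stressBetweenSD, pixelNoiseSD = pixelNoiseSD,
      causal = causal, rasterSize = as.integer(rasterSize))
}

#' @rdname syntheticCohortConfig
#' @export
defaultCausalSpec <- function() {
  data.frame(
    feature = c("STRESS_S14_MIN", "STRESS_S10_MIN", "STRESS_S15_MIN",
                "RESERVE_S14_MIN"),
    effect = c(-1, -1, -1, -1))
}

# floor on rest pixels so the pixelwise stress/rest reserve ratio stays
# finite and positive
.MINFLOW <- 0.05

#' Generate a synthetic perfusion cohort
#'
#' Patient i's 17 segment mean flows are drawn around the configured rest
#' and stress means; pixels add within-segment Gaussian noise (floored at a
#' small positive flow); the reserve map is the pixelwise stress/rest
#' ratio. The 663 features are then extracted with [buildFeatureVector()].
#' Event probabilities follow a logistic model on the standardized causal
#' statistics (standardization uses the generated cohort's own moments),
#' with the intercept solved numerically so the expected event rate equals
#' the configured prevalence; outcomes are Bernoulli draws.
#'
#' @param config a [SyntheticCohortConfig-class].
#' @param seed integer seed; generation is deterministic given the seed.
#' @param keepMaps logical; when `TRUE` the per-patient [PolarMap-class]
#'   triples are returned as well (memory-heavy for large cohorts).
#' @param geometry a [SegmentGeometry-class].
#' @return list with `features` (SummarizedExperiment with `MACE`),
#'   `truth` (list: intercept, linear predictor `eta`, event probabilities)
#'   and `maps` (list of per-patient lists, or NULL).
#' @export
setMethod("generateCohort", "SyntheticCohortConfig",
  function(config, seed, keepMaps = FALSE, geometry = segmentGeometry()) {
    set.seed(as.integer(seed))
    n <- config@nPatients
    sz <- config@rasterSize
    center <- c(sz + 1, sz + 1) / 2
    radius <- (sz - 1) / 2
    mask <- .discMask(c(sz, sz), center, radius)
    lab <- .segmentLabels(geometry, mask, center, radius)
    npix <- sum(mask)
    values <- matrix(NA_real_, n, 663L,
                     dimnames = list(NULL, canonicalFeatureNames()))
    maps <- if (keepMaps) vector("list", n) else NULL
    for (i in seq_len(n)) {
      segRest <- pmax(rnorm(17, config@restMean, config@restBetweenSD),
                      2 * .MINFLOW)
      segStress <- pmax(rnorm(17, config@stressMean,
                              config@stressBetweenSD), 2 * .MINFLOW)
      rest <- stress <- matrix(NA_real_, sz, sz)
      rest[mask] <- pmax(segRest[lab[mask]] +
                           rnorm(npix, 0, config@pixelNoiseSD), .MINFLOW)
      stress[mask] <- pmax(segStress[lab[mask]] +
                             rnorm(npix, 0, config@pixelNoiseSD), .MINFLOW)
      reserve <- stress / rest
      pmR <- polarMap(rest, "REST", center, radius, mask)
      pmS <- polarMap(stress, "STRESS", center, radius, mask)
      pmV <- polarMap(reserve, "RESERVE", center, radius, mask)
      values[i, ] <- buildFeatureVector(pmR, pmS, pmV, geometry)
      if (keepMaps)
        maps[[i]] <- list(REST = pmR, STRESS = pmS, RESERVE = pmV)
    }
    eta <- numeric(n)
    if (nrow(config@causal)) {
      for (r in seq_len(nrow(config@causal))) {
        v <- values[, config@causal$feature[r]]
        s <- sd(v)
        z <- if (s > 0) (v - mean(v)) / s else rep(0, n)
        eta <- eta + config@causal$effect[r] * z
      }
    }
    intercept <- tryCatch(
      uniroot(function(b) mean(plogis(b + eta)) - config@prevalence,
              lower = qlogis(config@prevalence) - 30,
              upper = qlogis(config@prevalence) + 30,
              tol = 1e-10)$root,
      error = function(e)
        stop("could not solve the intercept for prevalence ",
             config@prevalence, ": ", conditionMessage(e)))
    prob <- plogis(intercept + eta)
    y <- rbinom(n, 1L, prob)
    list(features = makeFeatureTable(values, mace = y),
         truth = list(intercept = intercept, eta = eta, prob = prob),
         maps = maps)
  })

#' Construct a ground-truth sum-of-sigmoids generator
#'
#' Builds a known generating model for recovery experiments: by default
#' four steep, well-separated decreasing sigmoids on the stress/reserve
#' minimum statistics. Each term's domain is the fixed window
#' `[t - 0.7, t + 1.3]` (about 2 mL/g/min of population spread with 35% of
#' uniformly sampled mass below the transition, emulating an abrupt
#' ischemic flow threshold). With offsets m = 0.6 A the noiseless decision
#' rule requires at least 3 of the 4 flows to be low, so it fires for
#' P(Binom(4, 0.35) >= 3) ~ 12.7% of patients; the default 5% label flips
#' raise the observed event rate to about 0.16.
#'
#' @param features feature names.
#' @param A,t,k,m sigmoid parameter vectors, recycled to
#'   `length(features)`.
#' @param window numeric length 2, the informative domain relative to `t`.
#' @param flipRate label noise epsilon in [0, 0.5).
#' @return a [GroundTruthSOS-class].
#' @export
groundTruthSOS <- function(features = defaultCausalSpec()$feature,
                           A = c(1, 0.9, 0.8, 1.1),
                           t = c(1.0, 1.1, 0.9, 1.5),
                           k = c(60, 70, 60, 50),
                           m = 0.6 * A,
                           window = c(-0.7, 1.3),
                           flipRate = 0.05) {
  p <- length(features)
  A <- rep_len(A, p); t <- rep_len(t, p)
  k <- rep_len(k, p); m <- rep_len(m, p)
  fits <- lapply(seq_len(p), function(i) {
    .newSigmoidFit(A = A[i], t = t[i], k = k[i], m = m[i], rmse = 0,
                   domain = t[i] + sort(window))
  })
  model <- new("SumOfSigmoidsModel", featureNames = as.character(features),
               fits = fits,
               provenance = list(source = "ground-truth generator"))
  new("GroundTruthSOS", model = model, flipRate = flipRate)
}

#' Sample a labelled feature table from a ground-truth model
#'
#' Causal features are drawn from `sampler` (by default uniformly over each
#' sigmoid's domain, which spans the transition region asymmetrically so
#' that 35% of the mass lies below the transition point); the label is
#' `H(sum of true sigmoids)`, flipped with probability `flipRate`. Nuisance
#' features are appended as independent standard normal noise under unused
#' canonical feature names.
#'
#' @param gt a [GroundTruthSOS-class].
#' @param n number of patients.
#' @param seed integer seed.
#' @param nNuisance number of nuisance features (default 50, the "small"
#'   preset; use 659 to match the full 663-column table).
#' @param sampler optional function(fit, n) returning n draws of a causal
#'   feature.
#' @return list with `features` (SummarizedExperiment with `MACE`),
#'   `scores` (true summed scores) and `cleanLabels` (pre-flip labels).
#' @export
setMethod("sampleFromGroundTruth", "GroundTruthSOS",
  function(gt, n, seed, nNuisance = 50L, sampler = NULL) {
    set.seed(as.integer(seed))
    model <- gt@model
    p <- length(model@featureNames)
    if (is.null(sampler))
      sampler <- function(fit, n) runif(n, fit@domain[1], fit@domain[2])
    X <- vapply(model@fits, sampler, numeric(n), n = n)
    X <- matrix(X, nrow = n, dimnames = list(NULL, model@featureNames))
    scores <- rowSums(vapply(seq_len(p), function(i)
      sigmoidValue(model@fits[[i]], X[, i]), numeric(n)))
    clean <- heaviside(scores)
    flip <- rbinom(n, 1L, gt@flipRate)
    y <- as.integer(xor(clean, flip))
    pool <- setdiff(canonicalFeatureNames(), model@featureNames)
    nNuisance <- min(as.integer(nNuisance), length(pool))
    noise <- matrix(rnorm(n * nNuisance), n,
                    dimnames = list(NULL, pool[seq_len(nNuisance)]))
    values <- cbind(X, noise)
    cd <- S4Vectors::DataFrame(patient_id = paste0("P", seq_len(n)),
                               MACE = y)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(features = t(values)), colData = cd)
    list(features = se, scores = scores, cleanLabels = clean)
  })
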