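suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

outcomesOf <- function(se) as.integer(colData(se)$MACE)

# three constant-valued maps sharing one disc
constantMapTriple <- function(size = 64, restVal = 0.9, stressVal = 2.2,
                              reserveVal = stressVal / restVal) {
  list(rest = polarMap(matrix(restVal, size, size), "REST"),
       stress = polarMap(matrix(stressVal, size, size), "STRESS"),
       reserve = polarMap(matrix(reserveVal, size, size), "RESERVE"))
}

randomMap <- function(size = 32, kind = "STRESS", lo = 0.2, hi = 3) {
  g <- matrix(runif(size * size, lo, hi), size, size)
  polarMap(g, kind)
}

# a random stump ensemble constructed directly (no training), for oracle
# checks of score curves and margins
randomEnsemble <- function(nModels, stumpsPerModel, features,
                           thetaRange = c(-2, 2)) {
  models <- lapply(seq_len(nModels), function(j) {
    nf <- length(features)
    f <- sample(features, stumpsPerModel, replace = TRUE)
    list(bias = 0, seed = j,
         stumps = data.frame(
           feature = f,
           theta = runif(stumpsPerModel, thetaRange[1], thetaRange[2]),
           vLeft = rnorm(stumpsPerModel, sd = 0.5),
           vRight = rnorm(stumpsPerModel, sd = 0.5),
           gain = rexp(stumpsPerModel)))
  })
  ranges <- rbind(lo = rep(thetaRange[1] - 1, length(features)),
                  hi = rep(thetaRange[2] + 1, length(features)))
  colnames(ranges) <- features
  new("StumpEnsemble", models = models, config = ensembleConfig(nModels),
      featureRanges = ranges, masterSeed = 0L)
}

# independent brute-force oracle for the mean bias-free margin: plain loops
# over every model and stump, no shared code with the implementation
bruteMargin <- function(ensemble, x) {
  total <- 0
  for (m in ensemble@models) {
    st <- m$stumps
    if (!nrow(st)) next
    for (r in seq_len(nrow(st))) {
      if (x[st$feature[r]] >= st$theta[r]) total <- total + st$vRight[r]
      else total <- total + st$vLeft[r]
    }
  }
  total / length(ensemble@models)
}

# independent brute-force score-curve evaluation for one feature
bruteCurveValue <- function(ensemble, feature, x) {
  total <- 0
  for (m in ensemble@models) {
    st <- m$stumps[m$stumps$feature == feature, , drop = FALSE]
    if (!nrow(st)) next
    for (r in seq_len(nrow(st))) {
      if (x >= st$theta[r]) total <- total + st$vRight[r]
      else total <- total + st$vLeft[r]
    }
  }
  total / length(ensemble@models)
}

# small random feature table with iid noise features and random labels
noiseFeatureSE <- function(n, p, prevalence = 0.2,
                           names = paste0("F", seq_len(p))) {
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, names))
  y <- rbinom(n, 1, prevalence)
  SummarizedExperiment(
    assays = list(features = t(X)),
    colData = S4Vectors::DataFrame(patient_id = paste0("P", seq_len(n)),
                                   MACE = y))
}

# one-feature linearly separable table
separableSE <- function(n = 100, threshold = 0) {
  x <- c(runif(n / 2, threshold - 2, threshold - 0.1),
         runif(n / 2, threshold + 0.1, threshold + 2))
  y <- as.integer(x > threshold)
  X <- cbind(SEP = x, N1 = rnorm(n), N2 = rnorm(n))
  SummarizedExperiment(
    assays = list(features = t(X)),
    colData = S4Vectors::DataFrame(patient_id = paste0("P", seq_len(n)),
                                   MACE = y))
}
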