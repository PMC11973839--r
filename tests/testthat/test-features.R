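test_that("a constant map has degenerate statistics in every segment", {
  pm <- polarMap(matrix(3.2, 64, 64), "STRESS")
  st <- segmentStatistics(pm, segmentGeometry())
  expect_equal(dim(st), c(17L, 13L))
  for (colName in c("MEAN", "MIN", "MAX", paste0("P", seq(10, 90, 10))))
    expect_equal(unname(st[, colName]), rep(3.2, 17))
  expect_equal(unname(st[, "SD"]), rep(0, 17))
})

test_that("percentiles match an independent sort-and-interpolate oracle", {
  # fill one segment with a shuffled 1..n ramp; the oracle interpolates
  # between closest order statistics by hand (no call to quantile())
  geo <- segmentGeometry()
  pm <- polarMap(matrix(1, 64, 64), "STRESS")
  seg <- segmentMask(geo, pm, 3)
  n <- sum(seg)
  set.seed(42)
  g <- pm@grid
  g[seg] <- sample(seq_len(n))
  pm2 <- polarMap(g, "STRESS")
  st <- segmentStatistics(pm2, geo)
  oracle <- function(sorted, p) {
    h <- (length(sorted) - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    sorted[lo] + (h - lo) * (sorted[hi] - sorted[lo])
  }
  sorted <- seq_len(n)
  for (d in 1:9)
    expect_equal(unname(st[3, paste0("P", 10 * d)]),
                 oracle(sorted, d / 10))
  expect_equal(unname(st[3, "MIN"]), 1)
  expect_equal(unname(st[3, "MAX"]), n)
  expect_equal(unname(st[3, "MEAN"]), mean(sorted))
})

test_that("percentiles are nondecreasing and bounded on random maps", {
  set.seed(7)
  geo <- segmentGeometry()
  for (i in 1:1000) {
    st <- segmentStatistics(randomMap(32), geo)
    pct <- st[, paste0("P", seq(10, 90, 10))]
    expect_true(all(t(apply(pct, 1, diff)) >= -1e-12))
    expect_true(all(st[, "MIN"] <= pct + 1e-12))
    expect_true(all(pct <= st[, "MAX"] + 1e-12))
  }
})

test_that("statistics are equivariant under affine intensity rescaling", {
  set.seed(11)
  geo <- segmentGeometry()
  pm <- randomMap(48)
  a <- 1.7; b <- 0.4
  pm2 <- polarMap(a * pm@grid + b, "STRESS")
  st1 <- segmentStatistics(pm, geo)
  st2 <- segmentStatistics(pm2, geo)
  affine <- setdiff(colnames(st1), "SD")
  expect_equal(st2[, affine], a * st1[, affine] + b, tolerance = 1e-12)
  expect_equal(st2[, "SD"], a * st1[, "SD"], tolerance = 1e-12)
})

test_that("NaN values inside the disc are rejected with pixel locations", {
  # the constructor already rejects non-finite values ...
  g <- matrix(1, 64, 64)
  g[32, 33] <- NaN
  expect_error(polarMap(g, "REST"), "finite")
  # ... and a map corrupted after construction is caught with locations
  pm <- polarMap(matrix(1, 64, 64), "REST")
  pm@grid[32, 33] <- NaN
  expect_error(segmentStatistics(pm, segmentGeometry()), "NaN.*32,33")
})

test_that("the feature vector has 663 canonically named, ordered entries", {
  maps <- constantMapTriple(size = 64, restVal = 1, stressVal = 2,
                            reserveVal = 2)
  fv <- buildFeatureVector(maps$rest, maps$stress, maps$reserve)
  expect_length(fv, 663L)
  expect_identical(names(fv), canonicalFeatureNames())
  expect_true("STRESS_S14_MIN" %in% names(fv))
  stress <- fv[startsWith(names(fv), "STRESS")]
  expect_true(all(stress %in% c(2, 0)))
  expect_true(all(fv[endsWith(names(fv), "_SD")] == 0))
})

test_that("mismatched map kinds or shapes are rejected", {
  maps <- constantMapTriple()
  expect_error(
    buildFeatureVector(maps$stress, maps$rest, maps$reserve), "kind")
  small <- polarMap(matrix(0.9, 48, 48), "REST")
  expect_error(
    buildFeatureVector(small, maps$stress, maps$reserve), "share")
})

test_that("feature tables round-trip through CSV with a stable header", {
  set.seed(3)
  vals <- matrix(runif(2 * 663), 2,
                 dimnames = list(NULL, canonicalFeatureNames()))
  se <- makeFeatureTable(vals, patientId = c("a", "b"), mace = c(0, 1))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeFeatureTable(se, f1)
  se2 <- readFeatureTable(f1)
  writeFeatureTable(se2, f2)
  expect_identical(readLines(f1)[1], readLines(f2)[1])
  expect_equal(assay(se2), assay(se), tolerance = 1e-12)
  expect_identical(outcomesOf(se2), c(0L, 1L))
})

test_that("polar maps round-trip through text files", {
  set.seed(5)
  pm <- randomMap(33, kind = "RESERVE")
  prefix <- tempfile()
  writePolarMap(pm, prefix)
  pm2 <- readPolarMap(prefix)
  expect_identical(pm2@kind, "RESERVE")
  expect_equal(pm2@grid[pm2@mask], pm@grid[pm@mask])
  expect_identical(pm2@mask, pm@mask)
})
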