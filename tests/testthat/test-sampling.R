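oneDSpectra <- function(v) SpectraSet(1500, matrix(v, ncol = 1),
                                      paste0("s", seq_along(v)))

test_that("Kennard-Stone reproduces hand-checked 1-D cases", {
  split <- kennardStone(oneDSpectra(c(0, 1, 10)), calibrationFraction = 2 / 3)
  expect_identical(split@calibrationIds, c("s1", "s3"))
  # tie between the points at distance 1 from each end: lower index wins
  split <- kennardStone(oneDSpectra(c(0, 1, 9, 10)), calibrationSize = 3)
  expect_identical(split@calibrationIds, c("s1", "s2", "s4"))
  # select n of n
  split <- kennardStone(oneDSpectra(c(0, 1, 9, 10)), calibrationSize = 4)
  expect_identical(split@calibrationIds, paste0("s", 1:4))
  expect_length(split@predictionIds, 0)
})

test_that("Kennard-Stone matches the brute-force greedy oracle", {
  set.seed(14)
  for (trial in 1:20) {
    n <- sample(5:8, 1)
    d <- sample(1:3, 1)
    X <- matrix(runif(n * d, 0, 10), n)
    m <- sample(3:(n - 1), 1)
    ss <- SpectraSet(seq(1100, by = 10, length.out = d), X,
                     paste0("s", 1:n))
    split <- kennardStone(ss, calibrationSize = m)
    expect_identical(split@calibrationIds,
                     paste0("s", ksOracle(X, m)))
  }
})

test_that("Kennard-Stone is permutation-covariant without ties", {
  set.seed(5)
  X <- matrix(rnorm(20 * 6), 20)
  ids <- sprintf("s%02d", 1:20)
  ss <- SpectraSet(seq(1100, by = 10, length.out = 6), X, ids)
  ref <- kennardStone(ss, calibrationFraction = 0.5)
  perm <- sample(20)
  ssp <- SpectraSet(seq(1100, by = 10, length.out = 6), X[perm, ], ids[perm])
  shuffled <- kennardStone(ssp, calibrationFraction = 0.5)
  expect_identical(sort(shuffled@calibrationIds), sort(ref@calibrationIds))
})

test_that("KS calibration sets spread wider than random subsets", {
  sim <- simulateSpectra(smallConfig(seed = 17))
  sp <- snv(sim$spectra)
  split <- kennardStone(sp, 2 / 3)
  X <- absorbance(sp)
  D <- as.matrix(dist(X))
  minPair <- function(ix) min(D[ix, ix][upper.tri(D[ix, ix])])
  cal <- match(split@calibrationIds, sampleIds(sp))
  ksMin <- minPair(cal)
  set.seed(1)
  randMins <- replicate(500, minPair(sample(nrow(X), length(cal))))
  expect_true(all(ksMin >= randMins))
})

test_that("KS calibration and prediction reference statistics are close", {
  # the split is representative in reference space when computed on the
  # spectra as acquired (shape-normalized distances shift the means; see
  # the methods vignette)
  sim <- simulateSpectra(fixtureConfig(seed = 2))
  split <- kennardStone(sim$spectra, 2 / 3)
  for (analyte in c("abts", "frap", "dpph")) {
    y <- referenceValues(sim$references, analyte)
    dmean <- abs(mean(y[split@calibrationIds]) - mean(y[split@predictionIds]))
    expect_lt(dmean, 0.5 * sd(y))
  }
})

test_that("default split arithmetic is round(fraction*n), overridable", {
  sim <- simulateSpectra(fixtureConfig(seed = 2))
  split <- kennardStone(sim$spectra, 2 / 3)
  expect_length(split@calibrationIds, 74)  # round(2/3 * 111)
  forced <- kennardStone(sim$spectra, calibrationSize = 75)
  expect_length(forced@calibrationIds, 75)
  expect_length(forced@predictionIds, 36)
})

test_that("clean fixture spectra pass Chauvenet screening", {
  sim <- simulateSpectra(fixtureConfig(seed = 1))
  rep <- mahalanobisOutliers(sim$spectra)
  expect_length(rep@flagged, 0)
  expect_true(all(rep@distances >= 0))
  expect_gt(rep@subspaceDims, 1)
})

test_that("a planted gross outlier is flagged by both rules", {
  sim <- simulateSpectra(smallConfig(seed = 4))
  X <- absorbance(sim$spectra)
  X[7, ] <- 10 * max(X)
  ss <- SpectraSet(wavelengths(sim$spectra), X, sampleIds(sim$spectra))
  for (rule in c("chauvenet", "quantile95")) {
    rep <- mahalanobisOutliers(ss, rule = rule)
    expect_true(sampleIds(ss)[7] %in% rep@flagged)
  }
})

test_that("near-identical spectra give near-equal distances and no flags", {
  set.seed(31)
  base <- sin(seq(0, 6, length.out = 200))
  X <- matrix(rep(base, each = 30), 30) + rnorm(30 * 200, sd = 1e-4)
  ss <- SpectraSet(seq(1100, by = 5, length.out = 200), X)
  rep <- mahalanobisOutliers(ss)
  expect_length(rep@flagged, 0)
  expect_lt(sd(rep@distances) / mean(rep@distances), 0.2)
})

test_that("outlier screening validates its inputs", {
  ss <- SpectraSet(c(1100, 1200), matrix(rnorm(8), 4))
  expect_error(mahalanobisOutliers(ss), "at least 5")
  sim <- simulateSpectra(smallConfig(seed = 1))
  expect_error(mahalanobisOutliers(sim$spectra, varianceKept = 0), "varianceKept")
  expect_error(mahalanobisOutliers(sim$spectra, varianceKept = 1.2), "varianceKept")
})
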