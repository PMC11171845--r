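test_that("EDF retention ratio honours its boundary conditions", {
  expect_equal(edfRatio(1, 100, 1557)$ratio, 1, tolerance = 1e-12)
  expect_identical(edfRatio(1, 100, 1557)$kept, 1557L)
  expect_identical(edfRatio(100, 100, 1557)$kept, 2L)
  expect_identical(edfRatio(50, 100, 1557)$kept, 58L)
  # closed form at an arbitrary interior point
  k <- log(1557 / 2) / 99
  expect_equal(edfRatio(37, 100, 1557)$ratio, exp(-k * 36), tolerance = 1e-12)
  expect_error(edfRatio(0, 100, 1557), "out of range")
  expect_error(edfRatio(1, 1, 10), "N must be")
})

test_that("CARS traces respect the EDF bound and shrink monotonically", {
  sim <- simulateSpectra(smallConfig(seed = 25))
  sp <- snv(sim$spectra)
  split <- kennardStone(sp, 2 / 3)
  X <- absorbance(sp)[match(split@calibrationIds, sampleIds(sp)), ]
  y <- referenceValues(sim$references, "abts")[split@calibrationIds]
  res <- carsSelect(X, y, carsConfig(nRuns = 40, seed = 2))
  kc <- res@trace$keptCount
  expect_true(all(diff(kc) <= 0))
  for (i in seq_along(kc))
    expect_lte(kc[i], edfRatio(i, 40, ncol(X))$kept)
  expect_identical(res@trace$bestRun, which.min(res@trace$rmsecv))
  # the winning subset is drawn from the variables active entering its run
  # (the coefficient-path column records the pre-update active set)
  expect_true(all(res@selectedIndices %in%
                    which(!is.na(res@trace$coefPath[, res@trace$bestRun]))))
  expect_equal(res@rmsecv, min(res@trace$rmsecv))
})

test_that("CARS is deterministic for a fixed seed", {
  sim <- simulateSpectra(smallConfig(seed = 26))
  X <- absorbance(snv(sim$spectra))
  y <- referenceValues(sim$references, "frap")
  a <- carsSelect(X, y, carsConfig(nRuns = 30, seed = 5, recordCoefPath = FALSE))
  b <- carsSelect(X, y, carsConfig(nRuns = 30, seed = 5, recordCoefPath = FALSE))
  expect_identical(a@selectedIndices, b@selectedIndices)
  expect_identical(a@trace$rmsecv, b@trace$rmsecv)
})

test_that("CARS recovers planted bands on a small noiseless fixture", {
  cfg <- syntheticConfig(nSamples = 60, gridPoints = 300, scatterMultSd = 0,
                         scatterAddSd = 0, seed = 27)
  sim <- simulateSpectra(cfg)
  y <- referenceValues(sim$references, "abts")
  res <- carsSelect(absorbance(sim$spectra), y,
                    carsConfig(nRuns = 50, seed = 3, recordCoefPath = FALSE))
  hits <- vapply(sim$groundTruth$componentBands, function(bands)
    any(unlist(bands) %in% res@selectedIndices), logical(1))
  expect_true(all(hits))
})

test_that("GA finds a single planted predictor among noise", {
  set.seed(42)
  X <- matrix(rnorm(40 * 50), 40)
  y <- X[, 17] + rnorm(40, sd = 0.05)
  cfg <- gaConfig(nRuns = 8, population = 20, generations = 15,
                  frequencyThreshold = 4, nRepeats = 1, cvFolds = 5,
                  maxLvs = 5, seed = 9)
  res <- gaSelect(X, y, cfg)
  expect_true(17 %in% res@selectedIndices)
  expect_identical(which.max(res@trace$frequency), 17L)
  expect_equal(max(res@trace$frequency), 8)
})

test_that("GA selection is deterministic and threshold-monotone", {
  set.seed(1)
  X <- matrix(rnorm(30 * 40), 30)
  y <- X[, 5] - X[, 21] + rnorm(30, sd = 0.1)
  base <- gaConfig(nRuns = 6, population = 16, generations = 10,
                   frequencyThreshold = 3, nRepeats = 1, cvFolds = 5,
                   maxLvs = 4, seed = 77)
  a <- gaSelect(X, y, base)
  b <- gaSelect(X, y, base)
  expect_identical(a@selectedIndices, b@selectedIndices)
  expect_identical(a@trace$frequency, b@trace$frequency)
  loose <- base; loose$frequencyThreshold <- 1L
  loosest <- base; loosest$frequencyThreshold <- 0L
  selLoose <- gaSelect(X, y, loose)@selectedIndices
  selLoosest <- gaSelect(X, y, loosest)@selectedIndices
  expect_true(all(a@selectedIndices %in% selLoose))
  # threshold 0 degenerates to "ever chosen", identical to threshold 1
  expect_identical(selLoosest, selLoose)
  tight <- base; tight$frequencyThreshold <- 7L  # > nRuns: nothing survives
  expect_error(gaSelect(X, y, tight), "decrease frequencyThreshold")
})

test_that("GA window binning expands selected bins to wavelength indices", {
  sim <- simulateSpectra(smallConfig(seed = 28))
  X <- absorbance(snv(sim$spectra))
  y <- referenceValues(sim$references, "dpph")
  cfg <- gaConfig(nRuns = 4, population = 12, generations = 8,
                  frequencyThreshold = 2, nRepeats = 1, cvFolds = 5,
                  maxLvs = 5, window = 8, seed = 31)
  res <- gaSelect(X, y, cfg)
  expect_identical(res@trace$window, 8L)
  # selected indices come in whole bins of the binning partition
  bins <- split(seq_len(ncol(X)), rep(seq_len(ceiling(ncol(X) / 8)),
                                      each = 8)[seq_len(ncol(X))])
  touched <- unique(rep(seq_along(bins),
                        lengths(bins))[match(res@selectedIndices,
                                             unlist(bins))])
  expect_setequal(res@selectedIndices, unlist(bins[touched]))
})
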