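test_that("clearance capacity follows the assay formula and is not clamped", {
  expect_equal(clearanceCapacity(0.70, 0.40, 0.05), 50.0)
  expect_equal(clearanceCapacity(0.70, 0.33, 0.33), 100.0)  # full scavenging
  expect_equal(clearanceCapacity(0.70, 0.75, 0.05), 0.0)    # zero scavenging
  # pathological inputs may leave [0, 100]
  expect_gt(clearanceCapacity(0.70, 0.10, 0.20), 100)
  expect_error(clearanceCapacity(0, 0.4, 0.05), "invalid measurement")
  expect_error(clearanceCapacity(-0.1, 0.4, 0.05), "invalid measurement")
})

test_that("clearance capacity is invariant to joint scaling of absorbances", {
  set.seed(1)
  for (i in 1:20) {
    a0 <- runif(1, 0.2, 1); a1 <- runif(1, 0, 1); a2 <- runif(1, 0, 0.5)
    s <- runif(1, 0.5, 4)
    expect_equal(clearanceCapacity(s * a0, s * a1, s * a2),
                 clearanceCapacity(a0, a1, a2))
  }
})

test_that("FRAP concentration inverts the standard curve with range flag", {
  r <- frapConcentration(0.0044)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "outOfRange"))
  r <- frapConcentration(0.1944)
  expect_equal(as.numeric(r), 100, tolerance = 1e-9)
  expect_false(attr(r, "outOfRange"))
  r <- frapConcentration(0.9544)
  expect_equal(as.numeric(r), 500, tolerance = 1e-9)
  expect_false(attr(r, "outOfRange"))
  # curve -> inverse identity to 1e-9 relative tolerance
  x <- c(50, 123.4, 250, 499.9)
  expect_equal(as.numeric(frapConcentration(0.0019 * x + 0.0044)), x,
               tolerance = 1e-9)
})

test_that("noiseless single-component spectra are scalar multiples", {
  cfg <- syntheticConfig(nSamples = 10, gridPoints = 120,
                         components = list(componentSpec(1500, 60, 0.5,
                                                         effectAbts = 1)),
                         scatterMultSd = 0, scatterAddSd = 0, noiseSd = 0,
                         assayNoiseSd = 0, seed = 4)
  sim <- simulateSpectra(cfg)
  X <- absorbance(sim$spectra)
  base <- X[1, ] / max(X[1, ])
  for (i in 2:nrow(X))
    expect_equal(X[i, ] / max(X[i, ]), base, tolerance = 1e-10)
  d <- svd(X)$d
  expect_lte(sum(d > 1e-10 * d[1]), 1)
})

test_that("noiseless multi-component absorbance rank <= component count", {
  cfg <- smallConfig(seed = 9, scatterMultSd = 0, scatterAddSd = 0,
                     noiseSd = 0)
  X <- absorbance(simulateSpectra(cfg)$spectra)
  d <- svd(X)$d
  expect_lte(sum(d > 1e-10 * d[1]), length(cfg$components))
})

test_that("simulation is bit-identical for a fixed seed", {
  a <- simulateSpectra(smallConfig(seed = 7))
  b <- simulateSpectra(smallConfig(seed = 7))
  expect_identical(absorbance(a$spectra), absorbance(b$spectra))
  expect_identical(referenceValues(a$references), referenceValues(b$references))
  expect_identical(a$groundTruth$concentrations, b$groundTruth$concentrations)
  c <- simulateSpectra(smallConfig(seed = 8))
  expect_false(identical(absorbance(a$spectra), absorbance(c$spectra)))
})

test_that("default fixture reference values fall in the observed assay ranges", {
  sim <- simulateSpectra(fixtureConfig(seed = 3))
  vals <- referenceValues(sim$references)
  expect_equal(nrow(vals), 111)
  expect_true(all(vals$abts >= 7.4 & vals$abts <= 11.7))
  expect_true(all(vals$frap >= 14.0 & vals$frap <= 47.7))
  expect_true(all(vals$dpph >= 11.4 & vals$dpph <= 30.2))
})

test_that("default grid has 1557 points uniform in wavenumber, ascending in nm", {
  cfg <- syntheticConfig()
  expect_length(cfg$grid, 1557)
  expect_true(all(diff(cfg$grid) > 0))
  expect_equal(range(cfg$grid), c(1000, 2500))
  wn <- 1e7 / cfg$grid
  expect_equal(max(abs(diff(diff(sort(wn))))), 0, tolerance = 1e-8)
})

test_that("ground truth covers every band of every effective component", {
  sim <- simulateSpectra(smallConfig(seed = 2))
  gt <- sim$groundTruth
  expect_length(gt$componentBands, 3)  # all defaults have nonzero effects
  for (bands in gt$componentBands)
    for (ix in bands) expect_true(all(ix %in% gt$informativeIndices))
})

test_that("generator validates its configuration", {
  expect_error(syntheticConfig(nSamples = 3), "nSamples")
  expect_error(syntheticConfig(noiseSd = -1), "sd parameters")
  expect_error(syntheticConfig(components = list()), "component")
  expect_error(
    syntheticConfig(components = list(componentSpec(900, 50, 1))),
    "within the wavelength grid")
  expect_error(componentSpec(1500, -1, 1), "widths")
  expect_error(componentSpec(1500, 10, 1, concLow = 2, concHigh = 1), "concLow")
})
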