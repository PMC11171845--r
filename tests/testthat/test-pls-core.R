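# deterministic fixture shared with an external NIPALS reference
# implementation (scikit-learn PLSRegression, scale=False), whose fitted
# values were computed once and frozen below
oracleX <- function() outer(1:20, 1:8, function(i, j) sin(i * j / 3) + cos(i + j))
oracleY <- function() {
  as.numeric(oracleX() %*% c(1, -0.5, 0.25, 0, 0.5, -0.25, 0.125, 0) +
               sin(1:20))
}

test_that("fitPls agrees with an independent NIPALS reference", {
  skFitted <- list(
    `1` = c(1.496202009553, 0.805961497417, -1.175729522883, -0.745463134594,
            -0.774175451600, 0.101467042640, 1.290333623888, 1.404794107540),
    `3` = c(1.542496749079, 0.810836812034, -1.101308725274, -0.401358933858,
            0.842585793826, 1.411408603939, 1.594244285847, 2.145646852819),
    `5` = c(1.596280916349, 0.658459181026, -0.731827627772, -0.128233230764,
            0.655424819866, 1.340908119826, 1.653594961011, 2.288207959903))
  X <- oracleX(); y <- oracleY()
  for (a in c(1, 3, 5)) {
    m <- fitPls(X, y, a)
    expect_equal(predictMatrix(m, X)[1:8], skFitted[[as.character(a)]],
                 tolerance = 1e-9)
  }
})

test_that("single-predictor PLS equals simple OLS regression", {
  set.seed(2)
  x <- rnorm(30); y <- 2 + 3 * x + rnorm(30, sd = 0.3)
  m <- fitPls(matrix(x, ncol = 1), y, 1)
  fit <- lm(y ~ x)
  expect_equal(predictMatrix(m, matrix(x, ncol = 1)),
               unname(fitted(fit)), tolerance = 1e-10)
})

test_that("full-rank PLS reaches the OLS solution on orthogonal columns", {
  set.seed(6)
  X <- qr.Q(qr(matrix(rnorm(30 * 4), 30)))
  y <- rnorm(30)
  # with X'X proportional to the identity the PLS Krylov space degenerates
  # and NIPALS reaches the OLS solution in fewer than p components
  m <- suppressWarnings(fitPls(X, y, 4))
  Xc <- scale(X, scale = FALSE)
  bOls <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  expect_equal(m@coefficients, as.numeric(bOls), tolerance = 1e-8)
})

test_that("noiseless linear responses are interpolated in the full-rank limit", {
  set.seed(7)
  X <- matrix(rnorm(25 * 6), 25)
  y <- as.numeric(X %*% c(1, -2, 0.5, 0, 3, 1)) + 4
  m <- fitPls(X, y, 6)
  expect_lt(max(abs(predictMatrix(m, X) - y)), 1e-8)
})

test_that("coefficients satisfy b = W (P'W)^{-1} q", {
  set.seed(9)
  X <- matrix(rnorm(40 * 50), 40)
  y <- rnorm(40)
  m <- fitPls(X, y, 8)
  b <- m@weights %*% solve(t(m@xLoadings) %*% m@weights, m@yLoadings)
  expect_equal(m@coefficients, as.numeric(b), tolerance = 1e-8)
})

test_that("predictions are scale-equivariant and permutation-covariant", {
  sim <- simulateSpectra(smallConfig(seed = 13))
  y <- referenceValues(sim$references, "dpph")
  tr <- trainPls(sim$spectra, y, preprocessorSpec("snv"), maxLvs = 8,
                 folds = 5)
  p1 <- predict(tr$model, sim$spectra)
  # scaling y scales predictions and errors by the same factor
  tr2 <- trainPls(sim$spectra, 3.5 * y, preprocessorSpec("snv"), maxLvs = 8,
                  folds = 5)
  expect_equal(predict(tr2$model, sim$spectra), 3.5 * p1, tolerance = 1e-8)
  expect_equal(tr2$cv@rmsecvByLv, 3.5 * tr$cv@rmsecvByLv, tolerance = 1e-8)
  # permuted samples give identically permuted predictions
  perm <- sample(sampleIds(sim$spectra))
  expect_equal(predict(tr$model, selectSamples(sim$spectra, perm)), p1[perm])
})

test_that("prediction refuses an incompatible wavelength axis", {
  sim <- simulateSpectra(smallConfig(seed = 13))
  y <- referenceValues(sim$references, "abts")
  tr <- trainPls(sim$spectra, y, preprocessorSpec("raw"), maxLvs = 5,
                 folds = 5)
  off <- SpectraSet(wavelengths(sim$spectra) + 0.5,
                    absorbance(sim$spectra), sampleIds(sim$spectra))
  expect_error(predict(tr$model, off), "incompatible axis")
})

test_that("leave-one-out CV matches brute-force refits", {
  set.seed(10)
  X <- matrix(rnorm(15 * 10), 15)
  y <- as.numeric(X %*% rnorm(10)) + rnorm(15, sd = 0.2)
  maxLvs <- 5
  cv <- crossValidate(X, y, maxLvs = maxLvs, folds = 15)
  manual <- sapply(seq_len(maxLvs), function(a) {
    errs <- sapply(seq_len(15), function(i) {
      m <- fitPls(X[-i, , drop = FALSE], y[-i], a)
      predictMatrix(m, X[i, , drop = FALSE]) - y[i]
    })
    sqrt(mean(errs^2))
  })
  expect_equal(cv@rmsecvByLv, manual, tolerance = 1e-10)
})

test_that("venetian folds are deterministic and recorded 1-based", {
  X <- matrix(rnorm(24 * 5), 24)
  y <- rnorm(24)
  cv1 <- crossValidate(X, y, maxLvs = 4, folds = 6)
  cv2 <- crossValidate(X, y, maxLvs = 4, folds = 6)
  expect_identical(cv1@rmsecvByLv, cv2@rmsecvByLv)
  expect_identical(cv1@foldAssignment, rep(1:6, 4))
  expect_identical(cv1@chosenLvs, which.min(cv1@rmsecvByLv))
})

test_that("pure-noise responses favour few latent variables", {
  set.seed(18)
  curves <- replicate(20, {
    X <- matrix(rnorm(40 * 80), 40)
    y <- rnorm(40)
    crossValidate(X, y, maxLvs = 10, folds = 10)@rmsecvByLv
  })
  meanCurve <- rowMeans(curves)
  expect_equal(which.min(meanCurve), 1L)
  expect_gt(cor(seq_along(meanCurve), meanCurve), 0)
})

test_that("noiseless three-component spectra need few latent variables", {
  cfg <- syntheticConfig(nSamples = 60, gridPoints = 400, scatterMultSd = 0,
                         scatterAddSd = 0, noiseSd = 0, assayNoiseSd = 0,
                         seed = 22)
  sim <- simulateSpectra(cfg)
  y <- referenceValues(sim$references, "abts")
  cv <- crossValidate(absorbance(sim$spectra), y, maxLvs = 10, folds = 10)
  expect_lte(cv@chosenLvs, 5)
})

test_that("fit preconditions are enforced", {
  X <- matrix(rnorm(20), 10)
  expect_error(fitPls(X, rep(1, 10), 1), "zero-variance")
  expect_error(fitPls(X, rnorm(10), 5), "nLvs must be between")
  expect_warning(crossValidate(matrix(rnorm(40), 10), rnorm(10),
                               maxLvs = 15, folds = 5), "reduced")
})
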