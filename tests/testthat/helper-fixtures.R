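# Shared fixtures for the test suite.  Everything is generated in code; no
# data files are read.

# independent brute-force implementation of the Kennard-Stone max-min
# greedy criterion (plain loops; the package uses a vectorized path)
ksOracle <- function(X, m) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  pair <- c(1, 2); bestD <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > bestD) { bestD <- D[i, j]; pair <- c(i, j) }
  sel <- pair
  while (length(sel) < m) {
    rest <- setdiff(1:n, sel)
    md <- sapply(rest, function(r) min(D[r, sel]))
    sel <- c(sel, rest[which.max(md)])
  }
  sort(sel)
}

# the default synthetic study fixture (111 samples, 1557-point grid)
fixtureConfig <- function(seed) syntheticConfig(seed = seed)

# a small, fast generator configuration for unit tests
smallConfig <- function(seed, ...) {
  syntheticConfig(nSamples = 40L, gridPoints = 160L, seed = seed, ...)
}

# scaled-down GA settings used on the full-size fixture: the published GA
# protocol (100 runs x 100 generations x 30 chromosomes on 1557 variables)
# is far beyond a desk-scale test budget, so the fixture GA uses 10 runs of
# 25 generations with 20 chromosomes on 8-point mean-binned spectra, with a
# proportionally reduced frequency threshold of 2
gaFixtureConfig <- function(seed) {
  gaConfig(nRuns = 10L, population = 20L, generations = 25L,
           frequencyThreshold = 2L, nRepeats = 1L, window = 8L,
           cvFolds = 5L, maxLvs = 10L, seed = seed)
}

# every printed (R2C, R2rand, cR2P) triple of the two published comparison
# tables: 15 pretreatment rows and 9 wavelength-selection rows
printedCr2pTriples <- function() {
  rbind(
    # pretreatment table: raw, 1D+SG, MSC, SNV, smoothing per analyte
    data.frame(analyte = "abts",
               r2c = c(0.806, 0.749, 0.837, 0.836, 0.801),
               r2rand = c(0.024, 0.049, 0.050, 0.042, 0.017),
               cr2p = c(0.79, 0.72, 0.81, 0.81, 0.79)),
    data.frame(analyte = "frap",
               r2c = c(0.855, 0.974, 0.888, 0.888, 0.851),
               r2rand = c(0.101, 0.126, 0.004, 0.127, 0.075),
               cr2p = c(0.80, 0.91, 0.89, 0.82, 0.81)),
    data.frame(analyte = "dpph",
               r2c = c(0.813, 0.833, 0.814, 0.831, 0.806),
               r2rand = c(0.075, 0.125, 0.060, 0.017, 0.100),
               cr2p = c(0.77, 0.77, 0.78, 0.82, 0.75)),
    # selector table: Full-PLS, GA-PLS, CARS-PLS per analyte
    data.frame(analyte = "abts",
               r2c = c(0.836, 0.852, 0.865),
               r2rand = c(0.042, 0.214, 0.164),
               cr2p = c(0.81, 0.74, 0.78)),
    data.frame(analyte = "frap",
               r2c = c(0.888, 0.872, 0.917),
               r2rand = c(0.127, 0.058, 0.082),
               cr2p = c(0.82, 0.84, 0.88)),
    data.frame(analyte = "dpph",
               r2c = c(0.831, 0.866, 0.866),
               r2rand = c(0.017, 0.019, 0.038),
               cr2p = c(0.82, 0.86, 0.85))
  )
}
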