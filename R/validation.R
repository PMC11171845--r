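#' Root-mean-square error
#'
#' `sqrt(mean((predicted - measured)^2))`, denominator `n`.  This is RMSEC
#' on calibration fits, RMSEP on prediction-set fits and RMSECV when pooled
#' over cross-validation held-out samples.
#'
#' @param measured,predicted numeric vectors of equal nonzero length
#' @return RMSE in the units of the response
#' @export
rmse <- function(measured, predicted) {
  if (length(measured) != length(predicted) || !length(measured))
    stop("measured and predicted must have equal nonzero length")
  sqrt(mean((predicted - measured)^2))
}

#' Squared Pearson correlation
#'
#' The "correlation coefficient" R2 of the NIR literature: the squared
#' Pearson correlation between measured and predicted values (not the
#' coefficient of determination; see [r2Determination()] for that).  Note
#' it is sign-blind -- anti-correlated predictions also give R2 = 1; the
#' [olsSlope()] catches that.
#'
#' @param measured,predicted non-constant numeric vectors
#' @return squared correlation in `[0, 1]`
#' @export
rSquared <- function(measured, predicted) {
  if (sd(measured) < 1e-14 || sd(predicted) < 1e-14)
    stop("degenerate metric: constant input vector")
  cor(measured, predicted)^2
}

#' @describeIn rSquared coefficient of determination,
#'   `1 - SS_res / SS_tot` (provided for completeness; the Pearson form is
#'   the package default and is what the gates use)
#' @export
r2Determination <- function(measured, predicted) {
  1 - sum((measured - predicted)^2) / sum((measured - mean(measured))^2)
}

#' OLS slope of predicted on measured
#'
#' Slope of the ordinary least-squares regression of predicted values on
#' measured values, intercept included.
#'
#' @param measured non-constant numeric vector
#' @param predicted numeric vector
#' @return the regression slope
#' @export
olsSlope <- function(measured, predicted) {
  if (sd(measured) < 1e-14) stop("degenerate metric: constant measured values")
  mc <- measured - mean(measured)
  sum(mc * (predicted - mean(predicted))) / sum(mc^2)
}

#' Roy's r2m metric
#'
#' `r2m = r2 * (1 - sqrt(r2 - r2_0))`, where `r2` is the squared Pearson
#' correlation between measured and predicted values and `r2_0` the
#' through-origin determination `1 - sum((y - k*yhat)^2) / sum((y - ybar)^2)`
#' with `k = sum(y*yhat) / sum(yhat^2)` (Roy convention).  Values of at
#' least 0.5 indicate acceptable agreement.  When numerical noise makes
#' `r2 < r2_0`, the radical is taken on `|r2 - r2_0|` with a warning.
#'
#' @param measured,predicted non-constant numeric vectors
#' @return the r2m value
#' @export
r2m <- function(measured, predicted) {
  r2 <- rSquared(measured, predicted)
  k <- sum(measured * predicted) / sum(predicted^2)
  r20 <- 1 - sum((measured - k * predicted)^2) /
    sum((measured - mean(measured))^2)
  delta <- r2 - r20
  if (delta < 0) {
    warning(sprintf("r2 (%.4f) < r2_0 (%.4f); using |r2 - r2_0|", r2, r20))
    delta <- abs(delta)
  }
  r2 * (1 - sqrt(delta))
}

#' y-randomization test
#'
#' Refits the PLS model on randomly permuted responses, keeping the same
#' latent-variable count and variable subset, and reports the calibration
#' R2 of each permuted refit.  A robust model shows `R2rand` far below its
#' real `R2C`.
#'
#' @param X calibration predictor matrix (already pretreated and subset)
#' @param y calibration response
#' @param nLvs latent-variable count of the real model
#' @param nPerm number of permutations (default 25)
#' @param seed RNG seed
#' @param perms optional list of explicit permutation index vectors
#'   (overrides `nPerm`/`seed`; an identity permutation reproduces `R2C`)
#' @return list with `r2Rand` (mean over permutations) and `perPerm`
#' @export
yRandomization <- function(X, y, nLvs, nPerm = 25L, seed = 1L, perms = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (sd(y) < 1e-12) stop("zero-variance response")
  if (is.null(perms)) {
    if (nPerm < 1) stop("nPerm must be >= 1")
    set.seed(seed)
    perms <- lapply(seq_len(nPerm), function(i) sample.int(length(y)))
  }
  per <- vapply(perms, function(ix) {
    yp <- y[ix]
    fit <- cppPlsFit(X, yp, as.integer(nLvs))
    pred <- as.numeric(sweep(X, 2, as.numeric(fit$xMean)) %*%
                         fit$B[, ncol(fit$B)] + fit$yMean)
    if (sd(pred) < 1e-14) 0 else cor(yp, pred)^2
  }, numeric(1))
  list(r2Rand = mean(per), perPerm = per)
}

#' y-randomization statistic cR2P
#'
#' `cR2P = sqrt(R2C) * sqrt(R2C - R2rand)`: the closer the permuted-response
#' R2 is to the real calibration R2, the smaller the statistic.  Values of
#' at least 0.5 indicate absence of chance correlation.
#'
#' @param r2c calibration R2 (in `[0, 1]`)
#' @param r2rand mean y-randomization R2 (must not exceed `r2c`)
#' @return the cR2P value
#' @examples
#' cr2p(0.836, 0.042)  # 0.8147...
#' @export
cr2p <- function(r2c, r2rand) {
  if (any(r2rand < 0) || any(r2c > 1) || any(r2rand > r2c))
    stop("require 0 <= r2rand <= r2c <= 1 (complex-valued guard)")
  sqrt(r2c) * sqrt(r2c - r2rand)
}

#' Relative RMSEP decrease between two models
#'
#' Percentage decrease of the prediction error of a reduced (wavelength-
#' selected) model relative to a full-spectrum model:
#' `100 * (rmsepFull - rmsepReduced) / rmsepFull`.
#'
#' @param rmsepFull RMSEP of the full-spectrum model
#' @param rmsepReduced RMSEP of the selected-wavelength model
#' @return percentage decrease (negative if the reduced model is worse)
#' @examples
#' rmsepDecrease(0.57, 0.51)  # 10.53 (2 dp)
#' @export
rmsepDecrease <- function(rmsepFull, rmsepReduced) {
  if (any(rmsepFull <= 0)) stop("rmsepFull must be > 0")
  100 * (rmsepFull - rmsepReduced) / rmsepFull
}

#' Assemble the full validation battery for one model
#'
#' Computes the standard comparison-table row: calibration R2C, RMSEC and
#' slope from the training fit, RMSECV at the chosen latent-variable count
#' from `cv`, the y-randomization block (mean R2rand over `nPerm` permuted
#' refits and cR2P), prediction R2P, RMSEP and slope on the held-out set,
#' and Roy's r2m on the prediction set.  Gate flags record r2m >= 0.5 and
#' cR2P >= 0.5.
#'
#' @param model a fitted [PLSModel-class]
#' @param calSpectra,calY calibration spectra and reference values
#' @param predSpectra,predY prediction spectra and reference values
#'   (disjoint from the calibration set)
#' @param cv the [CVResult-class] from which the model's LV count was chosen
#' @param nPerm,seed y-randomization settings
#' @param modelLabel label stored in the report (e.g. "Full-PLS")
#' @return an [EvaluationReport-class]
#' @export
evaluateModel <- function(model, calSpectra, calY, predSpectra, predY, cv,
                          nPerm = 25L, seed = 1L, modelLabel = "PLS") {
  if (length(intersect(sampleIds(calSpectra), sampleIds(predSpectra))))
    stop("calibration and prediction sets must be disjoint")
  calPred <- predict(model, calSpectra)
  predPred <- predict(model, predSpectra)
  prep <- applyPreprocessor(model@preprocessor, calSpectra)
  Xcal <- absorbance(prep)[, model@wavelengthIndices, drop = FALSE]
  yr <- yRandomization(Xcal, calY, model@nLvs, nPerm = nPerm, seed = seed)
  r2c <- rSquared(calY, calPred)
  report <- new("EvaluationReport",
    analyte = if (length(model@analyte)) model@analyte else "unknown",
    model = modelLabel,
    r2C = r2c, rmsec = rmse(calY, calPred),
    rmsecv = cv@rmsecvByLv[cv@chosenLvs],
    slopeC = olsSlope(calY, calPred),
    r2Rand = yr$r2Rand,
    cr2P = cr2p(r2c, min(yr$r2Rand, r2c)),
    r2P = rSquared(predY, predPred), rmsep = rmse(predY, predPred),
    slopeP = olsSlope(predY, predPred), r2m = r2m(predY, predPred),
    nCal = length(calY), nPred = length(predY), nLvs = model@nLvs,
    nVariables = length(model@wavelengthIndices),
    gates = c(r2m = NA, cr2p = NA))
  report@gates <- c(r2m = report@r2m >= 0.5, cr2p = report@cr2P >= 0.5)
  report
}
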