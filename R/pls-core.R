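#' Fit a PLS1 regression model
#'
#' NIPALS PLS1 on column-centered predictors and centered response.
#' Deterministic (no random initialisation); the predictor matrix is
#' deflated per component.  No unit-variance scaling is applied: centering
#' only, the NIR convention.
#'
#' @param X numeric matrix (samples x variables), already pretreated
#' @param y numeric response vector
#' @param nLvs number of latent variables (<= min(n - 1, p))
#' @param axis optional wavelength axis of the parent spectra (nm)
#' @param wavelengthIndices optional indices of `X`'s columns in the parent
#'   axis (default: all of it)
#' @param preprocessor optional frozen [preprocessorSpec()] recorded with
#'   the model
#' @param analyte optional analyte label
#' @return a [PLSModel-class]
#' @export
fitPls <- function(X, y, nLvs, axis = NULL, wavelengthIndices = NULL,
                   preprocessor = preprocessorSpec("raw"),
                   analyte = character()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y disagree on the number of samples")
  if (sd(y) < 1e-12) stop("zero-variance response")
  nLvs <- as.integer(nLvs)
  if (nLvs < 1 || nLvs > min(n - 1, p))
    stop("nLvs must be between 1 and min(n - 1, p) = ", min(n - 1, p))
  fit <- cppPlsFit(X, y, nLvs)
  a <- fit$achieved
  if (a < 1) stop("PLS extracted no components (response uncorrelated with X)")
  if (a < nLvs)
    warning(sprintf("only %d components extractable; nLvs reduced from %d", a, nLvs))
  nLvs <- min(nLvs, a)
  if (is.null(wavelengthIndices)) wavelengthIndices <- seq_len(p)
  if (is.null(axis)) axis <- as.numeric(seq_len(max(wavelengthIndices)))
  new("PLSModel", xMean = as.numeric(fit$xMean), yMean = fit$yMean,
      weights = fit$W[, seq_len(nLvs), drop = FALSE],
      xLoadings = fit$P[, seq_len(nLvs), drop = FALSE],
      yLoadings = as.numeric(fit$q)[seq_len(nLvs)],
      coefficients = as.numeric(fit$B[, nLvs]),
      nLvs = nLvs, wavelengthIndices = as.integer(wavelengthIndices),
      axis = as.numeric(axis), preprocessor = preprocessor,
      analyte = as.character(analyte))
}

#' @describeIn fitPls predict from a raw predictor matrix whose columns
#'   already match the model's variable subset (no pretreatment applied)
#' @param model a `PLSModel`
#' @export
predictMatrix <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model@xMean))
    stop("incompatible variable count: expected ", length(model@xMean))
  as.numeric(sweep(X, 2, model@xMean) %*% model@coefficients + model@yMean)
}

#' Predict reference values for new spectra
#'
#' Applies the model's frozen pretreatment, subsets to the model's
#' wavelengths, centers with the calibration means and returns
#' `X b + y_mean`.  The spectra's axis must match the model's parent axis
#' (same length, values within 1e-6 nm).
#'
#' @param object a [PLSModel-class]
#' @param spectra a `SpectraSet` on the model's parent wavelength axis
#' @return numeric vector of predictions named by sample ID
#' @export
setMethod("predict", "PLSModel", function(object, spectra) {
  stopifnot(is(spectra, "SpectraSet"))
  wl <- wavelengths(spectra)
  if (length(wl) != length(object@axis) ||
      max(abs(wl - object@axis)) > 1e-6)
    stop("incompatible axis: spectra do not match the model's wavelength grid")
  prep <- applyPreprocessor(object@preprocessor, spectra)
  X <- absorbance(prep)[, object@wavelengthIndices, drop = FALSE]
  stats::setNames(predictMatrix(object, X), sampleIds(spectra))
})

#' Cross-validated latent-variable selection
#'
#' K-fold cross-validation of PLS1 models with 1..`maxLvs` components.
#' Folds are venetian blinds by default (sample i in fold `i mod folds`),
#' which makes the procedure deterministic; set `shuffle = TRUE` with a
#' seed for randomized folds.  `RMSECV(k)` pools squared errors over all
#' held-out samples; the chosen count is the argmin, taking the smallest
#' count on ties (parsimony).
#'
#' @param X numeric matrix (samples x variables)
#' @param y numeric response
#' @param maxLvs largest component count to try (default 20; reduced with a
#'   warning when infeasible for the fold sizes)
#' @param folds number of folds (default 10, >= 2)
#' @param shuffle randomize the fold assignment?
#' @param seed seed used when `shuffle = TRUE`
#' @return a [CVResult-class]
#' @export
crossValidate <- function(X, y, maxLvs = 20L, folds = 10L,
                          shuffle = FALSE, seed = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- as.integer(folds)
  if (folds < 2) stop("folds must be >= 2")
  if (n < folds) stop("more folds than samples")
  assignment <- (seq_len(n) - 1L) %% folds
  if (shuffle) {
    if (!is.null(seed)) set.seed(seed)
    assignment <- sample(assignment)
  }
  trainSizes <- vapply(0:(folds - 1L), function(f) sum(assignment != f),
                       integer(1))
  cap <- min(as.integer(maxLvs), min(trainSizes) - 1L, ncol(X))
  if (cap < as.integer(maxLvs))
    warning(sprintf("maxLvs reduced from %d to %d (fold sizes / variables)",
                    as.integer(maxLvs), cap))
  if (cap < 1) stop("cross-validation infeasible: folds too small")
  rmsecv <- as.numeric(cppPlsCv(X, y, cap, folds, as.integer(assignment)))
  chosen <- which.min(rmsecv)
  new("CVResult", rmsecvByLv = rmsecv, chosenLvs = as.integer(chosen),
      foldAssignment = as.integer(assignment) + 1L)
}

#' Pretreat, cross-validate and fit a calibration model in one step
#'
#' Fits the pretreatment on the calibration spectra (freezing any
#' data-derived statistic), restricts to a wavelength subset if given,
#' selects the latent-variable count by cross-validation and fits the final
#' model.
#'
#' @param spectra calibration `SpectraSet`
#' @param y calibration reference values (same order as the spectra)
#' @param preprocessor a [preprocessorSpec()]
#' @param wavelengthIndices optional variable subset (indices into the axis)
#' @param maxLvs,folds passed to [crossValidate()]
#' @param analyte analyte label stored in the model
#' @return list with `model` ([PLSModel-class]) and `cv` ([CVResult-class])
#' @export
trainPls <- function(spectra, y, preprocessor = preprocessorSpec("snv"),
                     wavelengthIndices = NULL, maxLvs = 20L, folds = 10L,
                     analyte = character()) {
  fitted <- fitPreprocessor(preprocessor, spectra)
  X <- absorbance(fitted$spectra)
  if (is.null(wavelengthIndices)) wavelengthIndices <- seq_len(ncol(X))
  wavelengthIndices <- sort(unique(as.integer(wavelengthIndices)))
  X <- X[, wavelengthIndices, drop = FALSE]
  cv <- crossValidate(X, y, maxLvs = maxLvs, folds = folds)
  model <- fitPls(X, y, nLvs = cv@chosenLvs, axis = wavelengths(spectra),
                  wavelengthIndices = wavelengthIndices,
                  preprocessor = fitted$spec, analyte = analyte)
  list(model = model, cv = cv)
}
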