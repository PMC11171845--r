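#' Standard normal variate (SNV)
#'
#' Standardizes each spectrum to zero mean and unit standard deviation
#' (n-1 denominator), removing multiplicative and additive scatter effects
#' row-locally.
#'
#' @param spectra a `SpectraSet`
#' @return a `SpectraSet` of SNV-corrected spectra
#' @export
snv <- function(spectra) {
  X <- absorbance(spectra)
  sds <- apply(X, 1, sd)
  if (any(sds < 1e-12)) {
    bad <- sampleIds(spectra)[which(sds < 1e-12)[1]]
    stop("degenerate spectrum (constant absorbance): ", bad)
  }
  Xs <- (X - rowMeans(X)) / sds
  SpectraSet(wavelengths(spectra), Xs, sampleIds(spectra))
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum `x` on a reference spectrum by ordinary least
#' squares, `x ~ a + b * reference`, and replaces it by `(x - a) / b`.  The
#' reference defaults to the mean spectrum of the input set; for prediction
#' samples the calibration-set reference must be supplied (see
#' [fitPreprocessor()] which freezes it).
#'
#' @param spectra a `SpectraSet` with at least two wavelengths
#' @param reference optional reference spectrum; default = column mean
#' @return list with `spectra` (corrected `SpectraSet`) and `reference`
#'   (the reference actually used)
#' @export
msc <- function(spectra, reference = NULL) {
  X <- absorbance(spectra)
  if (ncol(X) < 2) stop("MSC requires at least 2 wavelengths")
  if (is.null(reference)) reference <- colMeans(X)
  if (length(reference) != ncol(X))
    stop("reference length does not match the wavelength axis")
  rc <- reference - mean(reference)
  if (sum(rc^2) < 1e-24) stop("degenerate fit: zero-variance MSC reference")
  # OLS of each row on the reference; with rc centered the slope reduces to
  # b = <x, rc> / <rc, rc> and the intercept to a = mean(x) - b * mean(ref)
  b <- as.numeric(X %*% rc) / sum(rc^2)
  a <- rowMeans(X) - b * mean(reference)
  if (any(abs(b) < 1e-12)) {
    bad <- sampleIds(spectra)[which(abs(b) < 1e-12)[1]]
    stop("degenerate fit: near-zero MSC slope for sample ", bad)
  }
  Xc <- (X - a) / b
  list(spectra = SpectraSet(wavelengths(spectra), Xc, sampleIds(spectra)),
       reference = as.numeric(reference))
}

# Savitzky-Golay projection matrices for one window: row 1 evaluates the
# fitted polynomial at each in-window position, rowDeriv its derivative.
sgBasis <- function(window, polyorder) {
  h <- (window - 1L) / 2L
  t <- seq(-h, h)
  A <- outer(t, 0:polyorder, `^`)
  G <- solve(crossprod(A), t(A))       # (polyorder+1) x window
  list(t = t, A = A, G = G)
}

sgApply <- function(X, window, polyorder, deriv = 0L) {
  p <- ncol(X)
  if (window %% 2L == 0L) stop("SG window must be odd")
  if (window <= polyorder) stop("SG window must exceed the polynomial order")
  if (window > p) stop("SG window exceeds the number of wavelengths")
  h <- (window - 1L) / 2L
  basis <- sgBasis(window, polyorder)
  # center coefficients: value (or 1st derivative) of the local fit at t = 0
  cc <- if (deriv == 0L) basis$G[1L, ] else basis$G[2L, ]
  out <- matrix(0, nrow(X), p)
  interior <- (h + 1L):(p - h)
  for (j in seq_len(window)) {
    cols <- interior + (j - h - 1L)
    out[, interior] <- out[, interior] + cc[j] * X[, cols, drop = FALSE]
  }
  # edges: fit the polynomial on the first/last full window and evaluate it
  # (or its derivative) at the edge positions -- no shortening
  coefL <- t(X[, seq_len(window), drop = FALSE] %*% t(basis$G))
  coefR <- t(X[, (p - window + 1L):p, drop = FALSE] %*% t(basis$G))
  evalPoly <- function(coef, t, deriv) {
    pow <- 0:(nrow(coef) - 1L)
    if (deriv == 0L) {
      as.numeric(t(coef) %*% t(outer(t, pow, `^`)))
    } else {
      dpow <- pmax(pow - 1L, 0L)
      as.numeric(t(coef * pow) %*% t(outer(t, dpow, `^`)))
    }
  }
  tl <- seq(-h, -1L)
  tr <- seq(1L, h)
  for (i in seq_len(nrow(X))) {
    out[i, seq_len(h)] <- evalPoly(coefL[, i, drop = FALSE], tl, deriv)
    out[i, (p - h + 1L):p] <- evalPoly(coefR[, i, drop = FALSE], tr, deriv)
  }
  out
}

#' Savitzky-Golay smoothing
#'
#' Local polynomial least-squares smoothing.  Interior points use the
#' centered window; the first and last half-windows are handled by fitting
#' the polynomial on the boundary window and evaluating it there, so the
#' output has the same length as the input.
#'
#' @param spectra a `SpectraSet`
#' @param window odd window length (default 11)
#' @param polyorder polynomial order (default 2, must be < window)
#' @return smoothed `SpectraSet`
#' @export
sgSmooth <- function(spectra, window = 11L, polyorder = 2L) {
  X <- sgApply(absorbance(spectra), as.integer(window), as.integer(polyorder), 0L)
  SpectraSet(wavelengths(spectra), X, sampleIds(spectra))
}

#' Savitzky-Golay first derivative
#'
#' First derivative of each spectrum with respect to wavelength (per-nm
#' units).  The derivative is computed on the index grid by the SG filter
#' and divided by the local axis spacing (central differences of the nm
#' axis), which is exact for a uniform grid and a good local approximation
#' on the slightly non-uniform nm grid of an FT instrument.
#'
#' @inheritParams sgSmooth
#' @return `SpectraSet` of first-derivative spectra (AU/nm)
#' @export
sgDerivative <- function(spectra, window = 11L, polyorder = 2L) {
  wl <- wavelengths(spectra)
  D <- sgApply(absorbance(spectra), as.integer(window), as.integer(polyorder), 1L)
  p <- length(wl)
  step <- numeric(p)
  step[1] <- wl[2] - wl[1]
  step[p] <- wl[p] - wl[p - 1]
  if (p > 2) step[2:(p - 1)] <- (wl[3:p] - wl[1:(p - 2)]) / 2
  D <- sweep(D, 2, step, "/")
  SpectraSet(wl, D, sampleIds(spectra))
}

#' Fit a pretreatment on calibration spectra
#'
#' Applies the pretreatment described by `spec` and freezes any data-derived
#' statistic so the identical transform can be replayed on prediction
#' spectra.  Only MSC has such a statistic (its reference spectrum, the
#' calibration column mean); all other methods are row-local.
#'
#' @param spec a [preprocessorSpec()]
#' @param spectra calibration `SpectraSet`
#' @return list with `spectra` (transformed set) and `spec` (frozen spec)
#' @export
fitPreprocessor <- function(spec, spectra) {
  stopifnot(is(spec, "PreprocessorSpec"))
  if (spec@method == "msc" && is.null(spec@mscReference)) {
    res <- msc(spectra)
    spec@mscReference <- res$reference
    return(list(spectra = res$spectra, spec = spec))
  }
  list(spectra = applyPreprocessor(spec, spectra), spec = spec)
}

#' Apply a frozen pretreatment
#'
#' Replays a pretreatment on new spectra.  For MSC the frozen calibration
#' reference must be present; it is never recomputed from the new data
#' (information-leakage guard).
#'
#' @param spec a (frozen) [preprocessorSpec()]
#' @param spectra a `SpectraSet`
#' @return transformed `SpectraSet`
#' @export
applyPreprocessor <- function(spec, spectra) {
  stopifnot(is(spec, "PreprocessorSpec"))
  switch(spec@method,
    raw = spectra,
    snv = snv(spectra),
    msc = {
      if (is.null(spec@mscReference))
        stop("MSC reference is not frozen; fit the preprocessor on calibration spectra first")
      msc(spectra, reference = spec@mscReference)$spectra
    },
    smoothing = sgSmooth(spectra, spec@sgWindow, spec@sgPolyorder),
    d1_sg = sgDerivative(spectra, spec@sgWindow, spec@sgPolyorder)
  )
}
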