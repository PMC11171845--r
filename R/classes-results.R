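setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' PreprocessorSpec: a serializable spectral pretreatment
#'
#' Describes one of the pretreatment families: `raw` (pass-through), `snv`,
#' `msc`, `smoothing` (Savitzky-Golay smoothing) and `d1_sg` (first
#' derivative with Savitzky-Golay polynomial filtering).  MSC estimates its
#' reference spectrum from the calibration set the first time it is fitted
#' and must reuse that frozen reference for any prediction-set transform;
#' the frozen reference lives in `mscReference`.
#'
#' @param method one of `"raw"`, `"snv"`, `"msc"`, `"smoothing"`, `"d1_sg"`
#' @param sgWindow odd Savitzky-Golay window length (default 11)
#' @param sgPolyorder Savitzky-Golay polynomial order (default 2)
#' @param mscReference optional frozen MSC reference spectrum
#' @return a `PreprocessorSpec`
#' @export
preprocessorSpec <- function(method = c("raw", "snv", "msc", "smoothing", "d1_sg"),
                             sgWindow = 11L, sgPolyorder = 2L,
                             mscReference = NULL) {
  method <- match.arg(method)
  new("PreprocessorSpec", method = method,
      sgWindow = as.integer(sgWindow), sgPolyorder = as.integer(sgPolyorder),
      mscReference = mscReference)
}

#' @rdname preprocessorSpec
#' @export
setClass("PreprocessorSpec",
         representation(method = "character", sgWindow = "integer",
                        sgPolyorder = "integer",
                        mscReference = "numericOrNULL"))

setValidity("PreprocessorSpec", function(object) {
  if (!object@method %in% c("raw", "snv", "msc", "smoothing", "d1_sg"))
    return("unknown pretreatment method")
  if (object@sgWindow %% 2L == 0L) return("sgWindow must be odd")
  if (object@sgWindow <= object@sgPolyorder)
    return("sgWindow must exceed sgPolyorder")
  TRUE
})

setMethod("show", "PreprocessorSpec", function(object) {
  cat("PreprocessorSpec:", object@method)
  if (object@method %in% c("smoothing", "d1_sg"))
    cat(sprintf(" (window %d, polyorder %d)", object@sgWindow, object@sgPolyorder))
  if (object@method == "msc")
    cat(if (is.null(object@mscReference)) " (reference unfrozen)" else " (reference frozen)")
  cat("\n")
})

#' PLSModel: a fitted PLS1 calibration model
#'
#' Stores everything needed to reproduce predictions from a file: centering
#' vectors, NIPALS weights/loadings, the regression coefficient vector on
#' centered data, the chosen latent-variable count, the wavelength subset the
#' model was fit on (indices into the parent axis, which is also stored), and
#' the frozen pretreatment.  The coefficient identity
#' `b = W (P'W)^{-1} q` holds to 1e-8.
#'
#' @seealso [fitPls()], [predict()][predict,PLSModel-method]
#' @export
setClass("PLSModel",
         representation(xMean = "numeric", yMean = "numeric",
                        weights = "matrix", xLoadings = "matrix",
                        yLoadings = "numeric", coefficients = "numeric",
                        nLvs = "integer", wavelengthIndices = "integer",
                        axis = "numeric", preprocessor = "PreprocessorSpec",
                        analyte = "character"))

setValidity("PLSModel", function(object) {
  if (object@nLvs < 1L) return("nLvs must be >= 1")
  if (length(object@coefficients) != length(object@xMean))
    return("coefficients and xMean lengths differ")
  if (length(object@wavelengthIndices) != length(object@xMean))
    return("wavelengthIndices and xMean lengths differ")
  TRUE
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel (%s): %d LVs on %d wavelengths; pretreatment %s\n",
              if (length(object@analyte)) object@analyte else "?",
              object@nLvs, length(object@wavelengthIndices),
              object@preprocessor@method))
})

#' @describeIn nirpls-generics number of latent variables of a `PLSModel`
#' @export
nLatentVariables <- function(x) x@nLvs

#' @rdname nirpls-generics
#' @export
setMethod("selectedWavelengths", "PLSModel", function(x, ...) {
  x@axis[x@wavelengthIndices]
})

#' CVResult: cross-validation curve and chosen latent-variable count
#'
#' `rmsecvByLv[k]` is the root-mean-square error of cross-validation of a
#' k-component model; `chosenLvs` is the argmin (lowest index on ties,
#' parsimony tie-break); `foldAssignment` records each sample's fold.
#' @export
setClass("CVResult",
         representation(rmsecvByLv = "numeric", chosenLvs = "integer",
                        foldAssignment = "integer"))

setValidity("CVResult", function(object) {
  cl <- object@chosenLvs
  if (cl < 1L || cl > length(object@rmsecvByLv)) return("chosenLvs out of range")
  if (which.min(object@rmsecvByLv) != cl)
    return("chosenLvs must be the argmin of rmsecvByLv")
  TRUE
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d LVs (RMSECV %.4g) out of %d tested\n",
              object@chosenLvs, min(object@rmsecvByLv),
              length(object@rmsecvByLv)))
})

#' SelectionResult: output of a wavelength selection run
#'
#' `selectedIndices` index the parent wavelength axis; `method` is `"ga"` or
#' `"cars"`; `rmsecv` is the cross-validated RMSE of a PLS model restricted
#' to the selected subset.  `trace` carries method-specific diagnostics: for
#' GA the per-wavelength selection frequencies over runs, for CARS the
#' per-run kept-variable counts, RMSECV values, the best run index and
#' (optionally) the regression-coefficient path.
#' @export
setClass("SelectionResult",
         representation(selectedIndices = "integer", method = "character",
                        rmsecv = "numeric", trace = "list", seed = "integer"))

setValidity("SelectionResult", function(object) {
  if (!length(object@selectedIndices)) return("selection is empty")
  if (anyDuplicated(object@selectedIndices)) return("duplicate indices")
  if (!object@method %in% c("ga", "cars")) return("method must be ga or cars")
  if (object@method == "cars") {
    kc <- object@trace$keptCount
    if (!is.null(kc) && any(diff(kc) > 0))
      return("CARS kept-count trace must be non-increasing")
  }
  TRUE
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s): %d wavelengths, subset RMSECV %.4g\n",
              object@method, length(object@selectedIndices), object@rmsecv))
})

#' OutlierReport: Mahalanobis-distance screening result
#'
#' Distances are computed in a PCA score subspace (see
#' [mahalanobisOutliers()]); `threshold` is on the distance scale and
#' `flagged` lists the sample IDs whose distance exceeds it.
#' @export
setClass("OutlierReport",
         representation(distances = "numeric", threshold = "numeric",
                        flagged = "character", subspaceDims = "integer",
                        rule = "character"))

setValidity("OutlierReport", function(object) {
  if (any(object@distances < 0)) return("distances must be >= 0")
  if (!all(object@flagged %in% names(object@distances)))
    return("flagged IDs must be among the scored samples")
  if (length(object@flagged) &&
      any(object@distances[object@flagged] <= object@threshold))
    return("every flagged distance must exceed the threshold")
  TRUE
})

setMethod("show", "OutlierReport", function(object) {
  cat(sprintf("OutlierReport (%s, %d PCs): %d/%d flagged (threshold %.3f)\n",
              object@rule, object@subspaceDims, length(object@flagged),
              length(object@distances), object@threshold))
})

#' SplitResult: calibration/prediction partition
#' @export
setClass("SplitResult",
         representation(calibrationIds = "character",
                        predictionIds = "character",
                        ratioRequested = "numeric"))

setValidity("SplitResult", function(object) {
  if (length(intersect(object@calibrationIds, object@predictionIds)))
    return("calibration and prediction sets must be disjoint")
  TRUE
})

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult: %d calibration / %d prediction samples\n",
              length(object@calibrationIds), length(object@predictionIds)))
})

#' EvaluationReport: the full validation battery for one model
#'
#' One row of the standard model-comparison table: calibration statistics
#' (R2C, RMSEC, RMSECV, slope), the y-randomization block (R2rand and
#' cR2P = sqrt(R2C)*sqrt(R2C - R2rand)), prediction statistics (R2P, RMSEP,
#' slope) and Roy's r2m.  Gate flags record whether r2m >= 0.5 and
#' cR2P >= 0.5.
#' @export
setClass("EvaluationReport",
         representation(analyte = "character", model = "character",
                        r2C = "numeric", rmsec = "numeric", rmsecv = "numeric",
                        slopeC = "numeric", r2Rand = "numeric", cr2P = "numeric",
                        r2P = "numeric", rmsep = "numeric", slopeP = "numeric",
                        r2m = "numeric", nCal = "integer", nPred = "integer",
                        nLvs = "integer", nVariables = "integer",
                        gates = "logical"))

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport [%s / %s] LVs=%d vars=%d\n",
              object@analyte, object@model, object@nLvs, object@nVariables))
  cat(sprintf("  calibration: R2C=%.3f RMSEC=%.3g RMSECV=%.3g slope=%.2f\n",
              object@r2C, object@rmsec, object@rmsecv, object@slopeC))
  cat(sprintf("  y-randomization: R2rand=%.3f cR2P=%.2f\n",
              object@r2Rand, object@cr2P))
  cat(sprintf("  prediction: R2P=%.3f RMSEP=%.3g slope=%.2f r2m=%.3f\n",
              object@r2P, object@rmsep, object@slopeP, object@r2m))
  cat(sprintf("  gates (r2m>=0.5, cR2P>=0.5): %s\n",
              paste(ifelse(object@gates, "pass", "FAIL"), collapse = ", ")))
})

#' Flatten an EvaluationReport to a one-row data frame
#'
#' Columns follow the conventional comparison-table order.
#' @param report an `EvaluationReport`
#' @return a one-row `data.frame`
#' @export
reportAsRow <- function(report) {
  stopifnot(is(report, "EvaluationReport"))
  data.frame(analyte = report@analyte, model = report@model,
             lvs = report@nLvs, variables = report@nVariables,
             r2_c = report@r2C, rmsec = report@rmsec, rmsecv = report@rmsecv,
             slope_c = report@slopeC, r2_rand = report@r2Rand,
             cr2_p = report@cr2P, r2_p = report@r2P, rmsep = report@rmsep,
             slope_p = report@slopeP, r2_m = report@r2m,
             n_cal = report@nCal, n_pred = report@nPred,
             stringsAsFactors = FALSE)
}
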