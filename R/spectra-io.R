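#' Read a spectra matrix from CSV
#'
#' Expected layout: header cell (1,1) `sample_id`, remaining header cells
#' the wavelengths in nm; one row per sample.  Gzip-compressed files
#' (`.gz`) are read transparently.  A descending wavelength axis is
#' re-sorted ascending (columns permuted accordingly) with a message.
#'
#' @param path path to a CSV (optionally `.gz`) file
#' @return a validated `SpectraSet`
#' @export
# fread with transparent gzip support that does not rely on extra packages
freadAuto <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    data.table::fread(text = readLines(con), ...)
  } else {
    data.table::fread(path, ...)
  }
}

readSpectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- freadAuto(path, header = TRUE, colClasses = list(character = 1L))
  if (ncol(dt) < 2) stop("format error: no wavelength columns in ", path)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids))
    stop("format error: duplicate sample ID '", ids[duplicated(ids)][1], "'")
  wl <- suppressWarnings(as.numeric(colnames(dt)[-1]))
  if (anyNA(wl))
    stop("format error: non-numeric wavelength header in column ",
         which(is.na(wl))[1] + 1L)
  X <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(X) || anyNA(X)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(X), nrow(X)))),
                 arr.ind = TRUE)
    stop(sprintf("format error: non-numeric or missing cell at row %d, column %d",
                 bad[1, 1], bad[1, 2] + 1L))
  }
  ord <- order(wl)
  if (any(diff(wl[ord]) <= 0))
    stop("format error: wavelength axis not strictly monotonic after sorting")
  if (!identical(ord, seq_along(wl))) {
    message("wavelength axis was not ascending; columns re-sorted")
    wl <- wl[ord]
    X <- X[, ord, drop = FALSE]
  }
  SpectraSet(wl, X, ids)
}

#' Write a spectra matrix to CSV
#'
#' Inverse of [readSpectra()]; round-trips within 1e-12.  A `.gz` extension
#' triggers transparent gzip compression.
#'
#' @param spectra a `SpectraSet`
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSpectra <- function(spectra, path) {
  X <- absorbance(spectra)
  dt <- data.table::as.data.table(X)
  data.table::setnames(dt, format(wavelengths(spectra), digits = 15,
                                  trim = TRUE, scientific = FALSE))
  dt <- cbind(data.table::data.table(sample_id = sampleIds(spectra)), dt)
  data.table::fwrite(dt, path, compress = "auto")
  invisible(path)
}

#' Read a reference-value table from CSV
#'
#' Columns: `sample_id` plus any subset of `abts`, `frap`, `dpph`.
#'
#' @param path path to a CSV (optionally `.gz`) file
#' @return a `ReferenceTable`; absent analytes are simply missing columns
#' @export
readReferences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- freadAuto(path, header = TRUE,
                  colClasses = list(character = "sample_id"))
  if (!"sample_id" %in% colnames(dt))
    stop("format error: missing 'sample_id' column in ", path)
  present <- intersect(c("abts", "frap", "dpph"), colnames(dt))
  if (!length(present)) stop("format error: no analyte columns in ", path)
  args <- c(list(sampleIds = dt$sample_id),
            stats::setNames(lapply(present, function(a) as.numeric(dt[[a]])),
                            present))
  do.call(ReferenceTable, args)
}

#' @rdname readReferences
#' @param references a `ReferenceTable`
#' @param path output path
#' @export
writeReferences <- function(references, path) {
  dt <- data.table::as.data.table(references@values)
  dt <- cbind(data.table::data.table(sample_id = sampleIds(references)), dt)
  data.table::fwrite(dt, path, compress = "auto")
  invisible(path)
}

jsonCon <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Serialize a fitted PLS model to JSON
#'
#' The JSON envelope stores all model fields (centering vectors, weights,
#' loadings, coefficients, LV count, wavelength subset and parent axis)
#' plus the frozen pretreatment, so prediction is reproducible from the
#' file alone; [loadModel()] inverts it (round-trip within 1e-12).
#'
#' @param model a [PLSModel-class]
#' @param path output path (`.json` or `.json.gz`)
#' @return `path`, invisibly
#' @export
saveModel <- function(model, path) {
  payload <- list(
    format = "nirpls-pls-model", version = "1",
    analyte = model@analyte,
    nLvs = model@nLvs,
    axis = model@axis,
    wavelengthIndices = model@wavelengthIndices,
    xMean = model@xMean, yMean = model@yMean,
    weights = model@weights, xLoadings = model@xLoadings,
    yLoadings = model@yLoadings, coefficients = model@coefficients,
    preprocessor = list(method = model@preprocessor@method,
                        sgWindow = model@preprocessor@sgWindow,
                        sgPolyorder = model@preprocessor@sgPolyorder,
                        mscReference = model@preprocessor@mscReference))
  con <- jsonCon(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              null = "null"), con)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  con <- jsonCon(path, "r")
  on.exit(close(con))
  obj <- jsonlite::fromJSON(paste(readLines(con), collapse = "\n"),
                            simplifyVector = TRUE)
  if (!identical(obj$format, "nirpls-pls-model"))
    stop("not a nirpls model file: ", path)
  pp <- preprocessorSpec(obj$preprocessor$method,
                         sgWindow = obj$preprocessor$sgWindow,
                         sgPolyorder = obj$preprocessor$sgPolyorder,
                         mscReference = obj$preprocessor$mscReference)
  new("PLSModel", xMean = as.numeric(obj$xMean), yMean = as.numeric(obj$yMean),
      weights = as.matrix(obj$weights), xLoadings = as.matrix(obj$xLoadings),
      yLoadings = as.numeric(obj$yLoadings),
      coefficients = as.numeric(obj$coefficients),
      nLvs = as.integer(obj$nLvs),
      wavelengthIndices = as.integer(obj$wavelengthIndices),
      axis = as.numeric(obj$axis), preprocessor = pp,
      analyte = as.character(obj$analyte))
}

#' Serialize an EvaluationReport to JSON
#'
#' @param report an [EvaluationReport-class]
#' @param path output path (`.json` or `.json.gz`)
#' @return `path`, invisibly
#' @export
writeReport <- function(report, path) {
  payload <- list(format = "nirpls-report", version = "1",
                  analyte = report@analyte, model = report@model,
                  metrics = list(r2_c = report@r2C, rmsec = report@rmsec,
                                 rmsecv = report@rmsecv, slope_c = report@slopeC,
                                 r2_rand = report@r2Rand, cr2_p = report@cr2P,
                                 r2_p = report@r2P, rmsep = report@rmsep,
                                 slope_p = report@slopeP, r2_m = report@r2m),
                  counts = list(n_cal = report@nCal, n_pred = report@nPred,
                                n_lvs = report@nLvs,
                                n_variables = report@nVariables),
                  gates = as.list(report@gates))
  con <- jsonCon(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE), con)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  con <- jsonCon(path, "r")
  on.exit(close(con))
  obj <- jsonlite::fromJSON(paste(readLines(con), collapse = "\n"))
  if (!identical(obj$format, "nirpls-report"))
    stop("not a nirpls report file: ", path)
  m <- obj$metrics; k <- obj$counts
  new("EvaluationReport", analyte = obj$analyte, model = obj$model,
      r2C = m$r2_c, rmsec = m$rmsec, rmsecv = m$rmsecv, slopeC = m$slope_c,
      r2Rand = m$r2_rand, cr2P = m$cr2_p, r2P = m$r2_p, rmsep = m$rmsep,
      slopeP = m$slope_p, r2m = m$r2_m,
      nCal = as.integer(k$n_cal), nPred = as.integer(k$n_pred),
      nLvs = as.integer(k$n_lvs), nVariables = as.integer(k$n_variables),
      gates = c(r2m = obj$gates$r2m, cr2p = obj$gates$cr2p))
}

#' Write the synthetic ground truth as a JSON sidecar
#'
#' Records the informative wavelength indices, the per-component band
#' windows, the drawn concentrations, the seed and an echo of the generator
#' configuration (scalar fields and components; the grid is summarized by
#' its endpoints and length).
#'
#' @param groundTruth the `groundTruth` element of [simulateSpectra()]'s
#'   return value
#' @param path output path (`.json` or `.json.gz`)
#' @return `path`, invisibly
#' @export
writeGroundTruth <- function(groundTruth, path) {
  cfg <- groundTruth$config
  echo <- list(nSamples = cfg$nSamples,
               gridPoints = length(cfg$grid),
               gridRange_nm = range(cfg$grid),
               scatterMultSd = cfg$scatterMultSd,
               scatterAddSd = cfg$scatterAddSd,
               noiseSd = cfg$noiseSd, assayNoiseSd = cfg$assayNoiseSd,
               targetRanges = cfg$targetRanges,
               components = lapply(cfg$components, unclass))
  payload <- list(format = "nirpls-ground-truth", version = "1",
                  seed = groundTruth$seed,
                  informativeIndices = groundTruth$informativeIndices,
                  componentBands = groundTruth$componentBands,
                  concentrations = groundTruth$concentrations,
                  config = echo)
  con <- jsonCon(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE), con)
  invisible(path)
}
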