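#' SpectraSet: NIR spectra with a wavelength axis
#'
#' An S4 container for a set of absorbance spectra sharing one wavelength
#' axis.  Internally a [SummarizedExperiment::SummarizedExperiment] with one
#' assay `"absorbance"` laid out wavelengths x samples; `rowData` carries the
#' axis in nm.  Chemometric code conventionally works with samples in rows,
#' so [absorbance()] returns the transposed `n_samples x n_wavelengths`
#' matrix with sample IDs as row names and wavelengths as column names.
#'
#' Validity requires a strictly ascending finite axis, finite absorbances,
#' and unique non-empty sample IDs.
#'
#' @param wavelengths numeric, strictly ascending wavelength axis in nm
#' @param absorbance numeric matrix, `n_samples x n_wavelengths`
#' @param sampleIds character vector of unique sample identifiers; defaults
#'   to the row names of `absorbance` or `sample_1 ... sample_n`
#' @return a `SpectraSet`
#' @examples
#' ss <- SpectraSet(c(1100, 1200, 1300), rbind(a = 1:3, b = c(2, 4, 6)))
#' wavelengths(ss)
#' absorbance(ss)
#' @export
SpectraSet <- function(wavelengths, absorbance, sampleIds = NULL) {
  if (is.vector(absorbance)) absorbance <- matrix(absorbance, nrow = 1)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (is.null(sampleIds)) {
    sampleIds <- rownames(absorbance)
    # rbind() tags unnamed rows with ""; fall back to generated IDs then
    if (is.null(sampleIds) || anyNA(sampleIds) || any(sampleIds == ""))
      sampleIds <- paste0("sample_", seq_len(nrow(absorbance)))
  }
  sampleIds <- as.character(sampleIds)
  mat <- t(absorbance)
  dimnames(mat) <- list(NULL, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = mat),
    rowData = S4Vectors::DataFrame(wavelength_nm = wavelengths)
  )
  new("SpectraSet", se)
}

#' @rdname SpectraSet
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  wl <- SummarizedExperiment::rowData(object)$wavelength_nm
  if (is.null(wl)) return("rowData must contain 'wavelength_nm'")
  if (!all(is.finite(wl))) return("wavelength axis must be finite")
  if (length(wl) > 1 && any(diff(wl) <= 0))
    return("wavelength axis must be strictly ascending")
  a <- SummarizedExperiment::assay(object, "absorbance")
  if (!all(is.finite(a))) return("absorbance values must be finite")
  ids <- colnames(object)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    return("sample IDs must be non-empty")
  if (anyDuplicated(ids))
    return(sprintf("duplicate sample ID: %s", ids[duplicated(ids)][1]))
  TRUE
})

#' @rdname nirpls-generics
#' @export
setMethod("wavelengths", "SpectraSet", function(x) {
  as.numeric(SummarizedExperiment::rowData(x)$wavelength_nm)
})

#' @rdname nirpls-generics
#' @export
setMethod("absorbance", "SpectraSet", function(x) {
  m <- t(SummarizedExperiment::assay(x, "absorbance"))
  colnames(m) <- NULL
  m
})

#' @rdname nirpls-generics
#' @export
setMethod("sampleIds", "SpectraSet", function(x) colnames(x))

setMethod("show", "SpectraSet", function(object) {
  wl <- wavelengths(object)
  cat("SpectraSet:", ncol(object), "samples x", nrow(object), "wavelengths\n")
  cat(sprintf("  axis: %.1f-%.1f nm\n", min(wl), max(wl)))
})

#' Subset a SpectraSet by sample ID
#'
#' @param x a `SpectraSet`
#' @param ids character vector of sample IDs to keep (order preserved)
#' @return a `SpectraSet` containing only the requested samples
#' @export
selectSamples <- function(x, ids) {
  missing <- setdiff(ids, sampleIds(x))
  if (length(missing))
    stop("unknown sample ID(s): ", paste(missing, collapse = ", "))
  x[, match(ids, sampleIds(x))]
}

#' Subset a SpectraSet to a set of wavelength indices
#'
#' @param x a `SpectraSet`
#' @param indices integer indices into the wavelength axis (will be sorted)
#' @return a `SpectraSet` restricted to those wavelengths
#' @export
selectWavelengthIndices <- function(x, indices) {
  indices <- sort(unique(as.integer(indices)))
  if (any(indices < 1L) || any(indices > nrow(x)))
    stop("wavelength indices out of range")
  x[indices, ]
}

#' ReferenceTable: per-sample assay reference values
#'
#' Holds the wet-chemistry reference values the calibration is built
#' against.  Any subset of the three analytes is permitted: `abts` (radical
#' clearance, %), `frap` (FeSO4-equivalent concentration, umol/L), `dpph`
#' (radical clearance, %).
#'
#' @param sampleIds unique sample identifiers
#' @param abts,frap,dpph numeric vectors (or NULL when the assay is absent)
#' @return a `ReferenceTable`
#' @examples
#' ReferenceTable(c("a", "b"), abts = c(9.1, 10.2), dpph = c(18, 22))
#' @export
ReferenceTable <- function(sampleIds, abts = NULL, frap = NULL, dpph = NULL) {
  sampleIds <- as.character(sampleIds)
  cols <- list(abts = abts, frap = frap, dpph = dpph)
  cols <- cols[!vapply(cols, is.null, logical(1))]
  if (!length(cols)) stop("at least one analyte column is required")
  df <- as.data.frame(lapply(cols, as.numeric))
  rownames(df) <- sampleIds
  new("ReferenceTable", sampleIds = sampleIds, values = df)
}

#' @rdname ReferenceTable
#' @export
setClass("ReferenceTable",
         representation(sampleIds = "character", values = "data.frame"))

setValidity("ReferenceTable", function(object) {
  if (anyDuplicated(object@sampleIds))
    return(sprintf("duplicate sample ID: %s",
                   object@sampleIds[duplicated(object@sampleIds)][1]))
  if (nrow(object@values) != length(object@sampleIds))
    return("values must have one row per sample ID")
  bad <- setdiff(colnames(object@values), c("abts", "frap", "dpph"))
  if (length(bad)) return(paste("unknown analyte column:", bad[1]))
  if (!all(vapply(object@values, function(v) all(is.finite(v)), logical(1))))
    return("reference values must be finite")
  TRUE
})

#' @rdname nirpls-generics
#' @export
setMethod("sampleIds", "ReferenceTable", function(x) x@sampleIds)

#' @rdname nirpls-generics
#' @export
setMethod("analytes", "ReferenceTable", function(x) colnames(x@values))

#' @rdname nirpls-generics
#' @param analyte optional analyte name; when given, returns that column as a
#'   named numeric vector, otherwise the full data frame
#' @export
setMethod("referenceValues", "ReferenceTable", function(x, analyte = NULL) {
  if (is.null(analyte)) return(x@values)
  analyte <- match.arg(analyte, c("abts", "frap", "dpph"))
  if (!analyte %in% colnames(x@values))
    stop("analyte '", analyte, "' is absent from this ReferenceTable")
  stats::setNames(x@values[[analyte]], x@sampleIds)
})

setMethod("show", "ReferenceTable", function(object) {
  cat("ReferenceTable:", length(object@sampleIds), "samples; analytes:",
      paste(analytes(object), collapse = ", "), "\n")
})

#' Units of the supported reference assays
#' @return named character vector of units per analyte
#' @export
analyteUnits <- function() c(abts = "%", frap = "umol/L", dpph = "%")

#' Align a ReferenceTable to the sample order of a SpectraSet
#'
#' Joins by sample ID so that shuffled file rows never change downstream
#' results.  Errors if any spectra sample lacks a reference row.
#'
#' @param spectra a `SpectraSet`
#' @param references a `ReferenceTable`
#' @return a `ReferenceTable` reordered to match `sampleIds(spectra)`
#' @export
alignReferences <- function(spectra, references) {
  ids <- sampleIds(spectra)
  missing <- setdiff(ids, sampleIds(references))
  if (length(missing))
    stop("no reference values for sample(s): ", paste(missing, collapse = ", "))
  idx <- match(ids, sampleIds(references))
  df <- references@values[idx, , drop = FALSE]
  do.call(ReferenceTable, c(list(sampleIds = ids), as.list(df)))
}
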