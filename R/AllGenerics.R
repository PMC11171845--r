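#' @title Generics for nirpls classes
#' @description Accessor generics shared by the spectra, reference-table and
#'   model classes.  Concrete methods are documented with their classes.
#' @param x,object an object of a nirpls class
#' @param ... passed to methods
#' @name nirpls-generics
NULL

#' @rdname nirpls-generics
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname nirpls-generics
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname nirpls-generics
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname nirpls-generics
#' @export
setGeneric("analytes", function(x) standardGeneric("analytes"))

#' @rdname nirpls-generics
#' @export
setGeneric("referenceValues", function(x, ...) standardGeneric("referenceValues"))

#' @rdname nirpls-generics
#' @export
setGeneric("selectedWavelengths", function(x, ...) standardGeneric("selectedWavelengths"))
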