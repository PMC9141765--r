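#' @title Generics for mitoCR classes
#' @description Accessor generics for the \code{Mitogenome} and
#'   \code{ControlRegion} classes.
#' @param x a \code{Mitogenome} or \code{ControlRegion} object
#' @name mitoCR-generics
NULL

#' @rdname mitoCR-generics
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @rdname mitoCR-generics
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname mitoCR-generics
#' @export
setGeneric("mtFeatures", function(x) standardGeneric("mtFeatures"))

#' @rdname mitoCR-generics
#' @export
setGeneric("taxonName", function(x) standardGeneric("taxonName"))

#' @rdname mitoCR-generics
#' @export
setGeneric("isCircularGenome", function(x) standardGeneric("isCircularGenome"))

#' @rdname mitoCR-generics
#' @export
setGeneric("crSeq", function(x) standardGeneric("crSeq"))

#' @rdname mitoCR-generics
#' @export
setGeneric("crLength", function(x) standardGeneric("crLength"))

#' @rdname mitoCR-generics
#' @export
setGeneric("crBounds", function(x) standardGeneric("crBounds"))
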