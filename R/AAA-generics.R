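#' @title Accessor generics
#' @description Generics for the core container classes.
#' @param object a promdiv object
#' @param ... further arguments for methods
#' @name promdiv-generics
#' @keywords internal
NULL

#' @rdname promdiv-generics
#' @export
setGeneric("sampleID", function(object) standardGeneric("sampleID"))

#' @rdname promdiv-generics
#' @export
setGeneric("librarySize", function(object) standardGeneric("librarySize"))

#' @rdname promdiv-generics
#' @export
setGeneric("ctss", function(object) standardGeneric("ctss"))

#' @rdname promdiv-generics
#' @export
setGeneric("clusters", function(object, ...) standardGeneric("clusters"))

#' @rdname promdiv-generics
#' @export
setGeneric("profiles", function(object) standardGeneric("profiles"))

#' @rdname promdiv-generics
#' @export
setGeneric("sampleTotals", function(object) standardGeneric("sampleTotals"))

#' @rdname promdiv-generics
#' @export
setGeneric("sampleCounts", function(object) standardGeneric("sampleCounts"))
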