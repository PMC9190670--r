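#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param x an object.
#' @return The slot value (see the method documentation on each class).
#' @name pedmeth-generics
#' @keywords internal
NULL

#' @rdname pedmeth-generics
#' @export
setGeneric("methScale", function(x) standardGeneric("methScale"))

#' @rdname pedmeth-generics
#' @export
setGeneric("methValues", function(x) standardGeneric("methValues"))

#' @rdname pedmeth-generics
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname pedmeth-generics
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))

#' @rdname pedmeth-generics
#' @export
setGeneric("eventType", function(x) standardGeneric("eventType"))

#' @rdname pedmeth-generics
#' @export
setGeneric("asM", function(x) standardGeneric("asM"))

#' @rdname pedmeth-generics
#' @export
setGeneric("asBeta", function(x) standardGeneric("asBeta"))
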