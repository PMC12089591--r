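#' Accessor generics
#'
#' Small accessor layer over the S4 containers: number and identifiers of IC
#' maps, mask grids, time-series matrices and connectome matrices are read
#' through these rather than through slots.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nMaps", function(x) standardGeneric("nMaps"))

#' @rdname accessors
#' @export
setGeneric("icIds", function(x) standardGeneric("icIds"))

#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname accessors
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))

#' @rdname accessors
#' @export
setGeneric("edgeMask", function(x) standardGeneric("edgeMask"))

#' @rdname accessors
#' @export
setGeneric("csfMask", function(x) standardGeneric("csfMask"))

#' @rdname accessors
#' @export
setGeneric("icMap", function(x, i) standardGeneric("icMap"))

#' @rdname accessors
#' @export
setGeneric("series", function(x) standardGeneric("series"))

#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("connMatrix", function(x) standardGeneric("connMatrix"))

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))
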