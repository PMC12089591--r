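#' @rdname accessors
setMethod("nMaps", "SpatialMapSet", function(x) dim(x@maps)[4])

#' @rdname accessors
setMethod("icIds", "SpatialMapSet", function(x) x@icIds)

#' @rdname accessors
setMethod("gridDim", "SpatialMapSet", function(x) dim(x@maps)[1:3])

#' @rdname accessors
setMethod("gridDim", "MaskSet", function(x) dim(x@brain))

#' @rdname accessors
setMethod("brainMask", "MaskSet", function(x) x@brain)

#' @rdname accessors
setMethod("edgeMask", "MaskSet", function(x) x@edge)

#' @rdname accessors
setMethod("csfMask", "MaskSet", function(x) x@csf)

#' @rdname accessors
#' @param i map index or IC identifier.
setMethod("icMap", "SpatialMapSet", function(x, i) {
  if (is.character(i)) i <- match(i, x@icIds)
  x@maps[, , , i]
})

#' @rdname accessors
setMethod("series", "NodeTimeSeries", function(x) x@series)

#' @rdname accessors
setMethod("repetitionTime", "NodeTimeSeries", function(x) x@tr)

#' @rdname accessors
setMethod("subjectId", "NodeTimeSeries", function(x) x@subject)

#' @rdname accessors
setMethod("subjectId", "Connectome", function(x) x@subject)

#' @rdname accessors
setMethod("connMatrix", "Connectome", function(x) x@matrix)

#' @rdname accessors
setMethod("nodeIds", "Connectome", function(x) x@nodeIds)

#' @rdname accessors
setMethod("coefTable", "GlmFit", function(x) x@coefficients)

setMethod("show", "MaskSet", function(object) {
  d <- gridDim(object)
  cat(sprintf("MaskSet on a %d x %d x %d grid (%.3g mm voxels)\n",
              d[1], d[2], d[3], object@voxelSize[1]))
  cat(sprintf("  brain: %d voxels | edge: %d | csf: %d\n",
              sum(object@brain), sum(object@edge), sum(object@csf)))
})

setMethod("show", "SpatialMapSet", function(object) {
  d <- dim(object@maps)
  cat(sprintf("SpatialMapSet: %d IC maps on a %d x %d x %d grid\n",
              d[4], d[1], d[2], d[3]))
})

setMethod("show", "NodeTimeSeries", function(object) {
  cat(sprintf("NodeTimeSeries '%s': %d timepoints x %d nodes (TR = %.3g s)\n",
              object@subject, nrow(object@series), ncol(object@series),
              object@tr))
})

setMethod("show", "Connectome", function(object) {
  cat(sprintf("Connectome '%s': %d x %d Pearson correlation matrix\n",
              object@subject, nrow(object@matrix), ncol(object@matrix)))
})

setMethod("show", "GlmFit", function(object) {
  cat(sprintf("GlmFit for '%s': %d edge predictors + %d covariates, n = %d\n",
              object@outcome, length(object@edgeTerms),
              length(object@covariates), object@nobs))
  print(object@coefficients, digits = 3, row.names = FALSE)
})
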