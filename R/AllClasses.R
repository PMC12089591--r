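#' @import methods
NULL

#' Binary mask set on a shared voxel grid
#'
#' Holds the three binary masks used by component quality control: the brain
#' mask (filled brain volume), the outer edge mask (one-ring shell produced by
#' dilating the brain mask and subtracting it) and the CSF mask (ventricular
#' interior). All three live on one grid.
#'
#' @slot brain,edge,csf 3-d binary (0/1) arrays of identical dimension.
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @export
setClass("MaskSet",
  representation(brain = "array", edge = "array", csf = "array",
                 voxelSize = "numeric"))

setValidity("MaskSet", function(object) {
  d <- dim(object@brain)
  if (length(d) != 3L) return("brain mask must be a 3-d array")
  if (!identical(d, dim(object@edge)) || !identical(d, dim(object@csf)))
    return("all masks must share one grid")
  for (nm in c("brain", "edge", "csf")) {
    v <- slot(object, nm)
    if (!all(v %in% c(0, 1))) return(sprintf("%s mask values must be 0/1", nm))
  }
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive lengths")
  TRUE
})

#' Set of volumetric IC spatial maps
#'
#' Real-valued spatial maps of independent components, stored as a 4-d array
#' whose fourth dimension indexes components. The grid must match the
#' [MaskSet-class] the maps are evaluated against.
#'
#' @slot maps 4-d array, `dim = c(grid, nIcs)`.
#' @slot icIds character vector of component identifiers.
#' @export
setClass("SpatialMapSet",
  representation(maps = "array", icIds = "character"))

setValidity("SpatialMapSet", function(object) {
  d <- dim(object@maps)
  if (length(d) != 4L) return("maps must be a 4-d array (x, y, z, ic)")
  if (d[4] != length(object@icIds)) return("icIds length must equal map count")
  if (anyDuplicated(object@icIds)) return("icIds must be unique")
  sums <- apply(abs(object@maps), 4, sum)
  if (any(sums == 0)) return("no map may be identically zero")
  TRUE
})

#' Per-subject node time series
#'
#' A T x N matrix of node signals for one subject, with the repetition time
#' needed for spectral features.
#'
#' @slot subject subject identifier.
#' @slot series numeric T x N matrix; columns are nodes.
#' @slot tr repetition time in seconds.
#' @export
setClass("NodeTimeSeries",
  representation(subject = "character", series = "matrix", tr = "numeric"))

setValidity("NodeTimeSeries", function(object) {
  if (!is.numeric(object@series)) return("series must be numeric")
  if (length(object@tr) != 1L || object@tr <= 0)
    return("tr must be a single positive number")
  TRUE
})

#' Functional connectome of one subject
#'
#' Symmetric N x N matrix of pairwise temporal Pearson correlations between
#' node time series, unit diagonal.
#'
#' @slot subject subject identifier.
#' @slot matrix numeric N x N correlation matrix.
#' @slot nodeIds character vector naming the N nodes.
#' @export
setClass("Connectome",
  representation(subject = "character", matrix = "matrix",
                 nodeIds = "character"))

setValidity("Connectome", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("connectome must be square")
  if (nrow(m) != length(object@nodeIds))
    return("nodeIds length must match matrix dimension")
  if (max(abs(m - t(m))) > 1e-12) return("connectome must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-12) return("diagonal must be 1")
  if (any(m < -1 - 1e-12 | m > 1 + 1e-12)) return("entries must lie in [-1, 1]")
  TRUE
})

#' Fitted covariate-adjusted general linear model
#'
#' Ordinary least-squares Gaussian GLM of one alcohol-intake outcome on the
#' selected connectome edges plus the confounder covariates, with
#' Holm-Bonferroni adjustment across the edge coefficients.
#'
#' @slot outcome name of the modelled outcome column.
#' @slot coefficients data.frame with columns `term`, `estimate`, `se`,
#'   `ciLow`, `ciHigh`, `p`, `pHolm` (Holm-adjusted p, `NA` for non-edge
#'   terms).
#' @slot edgeTerms character vector of the edge predictor names.
#' @slot covariates character vector of covariate predictor names.
#' @slot sigma residual standard deviation.
#' @slot nobs number of training observations.
#' @export
setClass("GlmFit",
  representation(outcome = "character", coefficients = "data.frame",
                 edgeTerms = "character", covariates = "character",
                 sigma = "numeric", nobs = "numeric"))

setValidity("GlmFit", function(object) {
  cf <- object@coefficients
  need <- c("term", "estimate", "se", "ciLow", "ciHigh", "p", "pHolm")
  if (!all(need %in% names(cf)))
    return(paste("coefficients must have columns:", paste(need, collapse = ", ")))
  if (any(cf$p < 0 | cf$p > 1, na.rm = TRUE)) return("p must lie in [0, 1]")
  if (any(cf$pHolm < cf$p - 1e-12, na.rm = TRUE))
    return("adjusted p must be >= raw p")
  if (any(cf$ciLow > cf$estimate + 1e-9 | cf$ciHigh < cf$estimate - 1e-9))
    return("CI must contain the estimate")
  TRUE
})
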