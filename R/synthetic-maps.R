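## Spatial side of the synthetic cohort: an ellipsoidal "brain" with an
## interior CSF compartment, its dilation-derived edge shell, and one smooth
## blob map per IC. Noise ICs get a fixed share of their absolute intensity
## planted in the edge or CSF compartment so that they violate exactly one
## quality-control threshold by construction.

ellipsoidMask <- function(gridShape, semi, centre = (gridShape + 1) / 2) {
  ax <- (seq_len(gridShape[1]) - centre[1]) / semi[1]
  ay <- (seq_len(gridShape[2]) - centre[2]) / semi[2]
  az <- (seq_len(gridShape[3]) - centre[3]) / semi[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  array(as.numeric(r2 <= 1), dim = gridShape)
}

gaussianBlob <- function(gridShape, centre, sigma) {
  dx <- (seq_len(gridShape[1]) - centre[1])^2
  dy <- (seq_len(gridShape[2]) - centre[2])^2
  dz <- (seq_len(gridShape[3]) - centre[3])^2
  array(exp(-outer(outer(dx, dy, `+`), dz, `+`) / (2 * sigma^2)),
        dim = gridShape)
}

## normalize a non-negative field to unit total absolute intensity
unitMass <- function(v) {
  s <- sum(abs(v))
  if (s == 0) stop("cannot normalize an all-zero field")
  v / s
}

#' Generate synthetic IC spatial maps, masks and ground truth
#'
#' Builds a filled-ellipsoid brain mask with an interior CSF compartment,
#' derives the outer edge mask with [makeEdgeMask()], and synthesizes one
#' smooth spatial map per IC. Signal ICs concentrate >= 90% of absolute
#' intensity inside brain-minus-CSF; ICs designated "edge" noise carry 60% of
#' their intensity in the edge shell (> the 0.4 threshold) and "csf" noise ICs
#' 50% in the CSF compartment (> the 0.3 threshold). RP- and
#' high-frequency-noise ICs are spatially signal-like (their violation is
#' temporal, planted by [genTimeseries()]).
#'
#' @param config a [syntheticConfig()].
#' @return list with elements `maps` ([SpatialMapSet-class]), `masks`
#'   ([MaskSet-class]) and `truth` (`GroundTruth`).
#' @export
genSpatialMaps <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  g <- config$gridShape
  set.seed(config$seed + 1L)
  brain <- ellipsoidMask(g, semi = 0.40 * g)
  csf <- ellipsoidMask(g, semi = 0.13 * g)
  if (sum(csf) == 0 || sum(brain) == 0 || sum(brain) == prod(g) ||
      sum(brain & !csf) < 8)
    stop("grid too small to hold a brain ellipsoid with an interior CSF region")
  edge <- makeEdgeMask(brain, 1L)
  if (sum(edge) == 0)
    stop("grid too small: brain ellipsoid leaves no room for an edge shell")
  masks <- new("MaskSet", brain = brain, edge = edge, csf = csf,
               voxelSize = c(2, 2, 2))

  core <- (brain == 1) & (csf == 0)            # edge shell is outside brain
  coreIdx <- which(core, arr.ind = TRUE)
  nIcs <- config$nNodes
  noiseType <- rep("signal", nIcs)
  for (tp in names(config$noiseIcs)) noiseType[config$noiseIcs[[tp]]] <- tp

  networks <- paste0("net", 1:8)
  label <- rep(NA_character_, nIcs)
  label[noiseType == "signal"] <-
    rep_len(networks, sum(noiseType == "signal"))

  maps <- array(0, dim = c(g, nIcs))
  smoothField <- function(mask) {
    # smooth positive field restricted to a compartment
    f <- gaussianBlob(g, centre = coreIdx[sample(nrow(coreIdx), 1), ] +
                        stats::rnorm(3, 0, 1), sigma = 0.35 * min(g))
    f <- f + 0.05 * mean(f)
    f * mask
  }
  for (k in seq_len(nIcs)) {
    ctr <- coreIdx[sample(nrow(coreIdx), 1), ]
    blob <- unitMass(gaussianBlob(g, ctr, sigma = 0.09 * min(g)) * core)
    spread <- unitMass(array(1, dim = g))      # diffuse residual intensity
    m <- switch(noiseType[k],
      edge = 0.6 * unitMass(smoothField(edge == 1)) + 0.4 * blob,
      csf  = 0.5 * unitMass(smoothField(csf == 1)) + 0.5 * blob,
      0.95 * blob + 0.05 * spread)
    maps[, , , k] <- m
  }
  mapSet <- new("SpatialMapSet", maps = maps,
                icIds = paste0("node", seq_len(nIcs)))
  truth <- structure(list(
    noiseType = noiseType,
    noiseFlags = noiseType != "signal",
    plantedEdges = config$plantedEdges,
    outcomeSpec = config$outcomeSpec,
    networkLabel = label), class = "GroundTruth")
  list(maps = mapSet, masks = masks, truth = truth)
}

#' Reference network maps from a labelled map set
#'
#' Averages the spatial maps of all ICs sharing a network label; used as the
#' labelled reference set for [assignNetworks()] recovery tests.
#'
#' @param mapSet a [SpatialMapSet-class].
#' @param labels character labels per IC (`NA` ICs are skipped).
#' @return a [SpatialMapSet-class] whose `icIds` are the unique labels.
#' @export
makeReferenceMaps <- function(mapSet, labels) {
  stopifnot(length(labels) == nMaps(mapSet))
  keep <- !is.na(labels)
  labs <- unique(labels[keep])
  g <- gridDim(mapSet)
  ref <- array(0, dim = c(g, length(labs)))
  for (k in seq_along(labs)) {
    idx <- which(keep & labels == labs[k])
    ref[, , , k] <- apply(mapSet@maps[, , , idx, drop = FALSE], 1:3, mean)
  }
  new("SpatialMapSet", maps = ref, icIds = labs)
}
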