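#' Quality-control thresholds for IC classification
#'
#' An IC is classified as signal only if its subject-mean feature values sit
#' at or below all four thresholds (each feature measures a noise signature;
#' boundaries are inclusive).
#'
#' @param maxRpCorr maximum realignment-parameter correlation threshold.
#' @param hfContent high-frequency (> 0.1 Hz) power-fraction threshold.
#' @param edgeFraction edge-mask intensity-fraction threshold.
#' @param csfFraction CSF-mask intensity-fraction threshold.
#' @return list of class `QcThresholds`.
#' @export
qcThresholds <- function(maxRpCorr = 0.5, hfContent = 0.3,
                         edgeFraction = 0.4, csfFraction = 0.3) {
  th <- list(maxRpCorr = maxRpCorr, hfContent = hfContent,
             edgeFraction = edgeFraction, csfFraction = csfFraction)
  if (any(unlist(th) <= 0 | unlist(th) >= 1))
    stop("thresholds must lie in (0, 1)")
  class(th) <- "QcThresholds"
  th
}

## binary dilation by shifting; connectivity 6 (faces), 18 (+edges) or
## 26 (+corners)
dilationOffsets <- function(connectivity) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  off[keep, , drop = FALSE]
}

shiftArray <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, dim = d)
  sx <- intersect(seq_len(d[1]), seq_len(d[1]) - dx)
  sy <- intersect(seq_len(d[2]), seq_len(d[2]) - dy)
  sz <- intersect(seq_len(d[3]), seq_len(d[3]) - dz)
  out[sx + dx, sy + dy, sz + dz] <- a[sx, sy, sz]
  out
}

#' Binary mask dilation
#'
#' @param mask 3-d binary array.
#' @param iterations number of dilation passes.
#' @param connectivity structuring element: 6 (faces), 18 or 26 neighbours.
#' @return dilated binary array.
#' @export
dilateMask <- function(mask, iterations = 1L, connectivity = 6L) {
  stopifnot(length(dim(mask)) == 3, iterations >= 1)
  off <- dilationOffsets(connectivity)
  out <- mask
  for (it in seq_len(iterations)) {
    acc <- out
    for (k in seq_len(nrow(off)))
      acc <- acc + shiftArray(out, off$dx[k], off$dy[k], off$dz[k])
    out <- array(as.numeric(acc > 0), dim = dim(mask))
  }
  out
}

#' Outer edge mask of a brain mask
#'
#' Dilates the binary brain mask and subtracts the original, leaving the
#' one-ring (per iteration) shell along the brain's outer boundary.
#'
#' @inheritParams dilateMask
#' @param brainMask 3-d binary array; must be non-empty.
#' @return binary array, disjoint from `brainMask`.
#' @export
makeEdgeMask <- function(brainMask, iterations = 1L, connectivity = 6L) {
  if (sum(brainMask) == 0) stop("brain mask is empty")
  dil <- dilateMask(brainMask, iterations, connectivity)
  edge <- dil - brainMask
  if (sum(edge) == 0)
    warning("brain mask fills the grid; edge mask is empty")
  edge
}

#' Fraction of a map's absolute intensity inside a mask
#'
#' @param icMap real-valued volume (IC spatial map; maps are signed, so
#'   absolute intensities are used).
#' @param mask binary volume on the same grid.
#' @return sum(|map|) over mask voxels / sum(|map|) over all voxels.
#' @export
fractionInMask <- function(icMap, mask) {
  if (!identical(dim(icMap), dim(mask)))
    stop("map and mask must share a grid")
  tot <- sum(abs(icMap))
  if (tot == 0) stop("all-zero map: intensity fraction undefined")
  sum(abs(icMap)[mask == 1]) / tot
}

#' Maximum absolute correlation with the realignment parameters
#'
#' @param icTimecourse numeric vector, length T >= 3, non-constant.
#' @param rp T x 6 matrix of realignment-parameter series.
#' @return max over columns of |Pearson r(timecourse, column)|.
#' @export
maxRpCorrelation <- function(icTimecourse, rp) {
  rp <- as.matrix(rp)
  if (length(icTimecourse) < 3) stop("need at least 3 timepoints")
  if (nrow(rp) != length(icTimecourse))
    stop("timecourse and realignment parameters differ in length")
  if (stats::sd(icTimecourse) == 0 || any(apply(rp, 2, stats::sd) == 0))
    stop("constant series: RP correlation undefined")
  max(abs(stats::cor(icTimecourse, rp)))
}

#' Welch power spectral density (averaged modified periodogram)
#'
#' Hann-windowed segments of length `segLength` with 50% overlap, per-segment
#' mean removal; one-sided spectrum.
#'
#' @param x numeric series.
#' @param tr sampling interval in seconds.
#' @param segLength segment length (default min(256, length(x))).
#' @return list with `freq` (Hz) and `power`.
#' @export
welchPsd <- function(x, tr, segLength = min(256L, length(x))) {
  n <- length(x)
  L <- min(segLength, n)
  step <- max(1L, floor(L / 2))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))
  acc <- numeric(floor(L / 2) + 1L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2
    acc <- acc + p[seq_len(floor(L / 2) + 1L)]
  }
  list(freq = (seq_len(floor(L / 2) + 1L) - 1L) / (L * tr),
       power = acc / length(starts))
}

#' High-frequency content of an IC time course
#'
#' Fraction of Welch spectral power at frequencies above `cutoffHz`.
#'
#' @param icTimecourse numeric series, length >= 64.
#' @param tr repetition time in seconds.
#' @param cutoffHz band cutoff (must be below Nyquist = 1/(2 tr)).
#' @param segLength Welch segment length.
#' @return power fraction in \[0, 1\].
#' @export
highFreqContent <- function(icTimecourse, tr, cutoffHz = 0.1,
                            segLength = min(256L, length(icTimecourse))) {
  if (length(icTimecourse) < 64) stop("need at least 64 timepoints")
  if (tr <= 0) stop("tr must be positive")
  if (cutoffHz >= 1 / (2 * tr))
    stop("cutoff must be below the Nyquist frequency 1/(2*tr)")
  psd <- welchPsd(icTimecourse, tr, segLength)
  tot <- sum(psd$power)
  if (tot == 0) stop("constant series: spectral fraction undefined")
  sum(psd$power[psd$freq > cutoffHz]) / tot
}

#' Compute the four quality-control features per (subject, IC)
#'
#' @param mapSet a [SpatialMapSet-class] of group IC maps.
#' @param maskSet a [MaskSet-class] on the same grid.
#' @param tsList list of [NodeTimeSeries-class], one per subject, whose
#'   columns align with the maps.
#' @param rpList list of T x 6 realignment-parameter matrices, parallel to
#'   `tsList`.
#' @param cutoffHz high-frequency cutoff in Hz.
#' @return data.frame with columns `subject`, `ic`, `edgeFraction`,
#'   `csfFraction`, `maxRpCorr`, `hfContent`.
#' @export
computeIcFeatures <- function(mapSet, maskSet, tsList, rpList,
                              cutoffHz = 0.1) {
  if (!identical(unname(gridDim(mapSet)), unname(gridDim(maskSet))))
    stop("maps and masks must share a grid")
  if (length(tsList) != length(rpList))
    stop("tsList and rpList must be parallel")
  nIcs <- nMaps(mapSet)
  eFrac <- cFrac <- numeric(nIcs)
  for (k in seq_len(nIcs)) {
    eFrac[k] <- fractionInMask(icMap(mapSet, k), edgeMask(maskSet))
    cFrac[k] <- fractionInMask(icMap(mapSet, k), csfMask(maskSet))
  }
  out <- lapply(seq_along(tsList), function(s) {
    X <- series(tsList[[s]])
    if (ncol(X) != nIcs) stop("time-series columns must match map count")
    data.frame(
      subject = subjectId(tsList[[s]]),
      ic = icIds(mapSet),
      edgeFraction = eFrac,
      csfFraction = cFrac,
      maxRpCorr = vapply(seq_len(nIcs), function(k)
        maxRpCorrelation(X[, k], rpList[[s]]), numeric(1)),
      hfContent = vapply(seq_len(nIcs), function(k)
        highFreqContent(X[, k], repetitionTime(tsList[[s]]), cutoffHz),
        numeric(1)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Aggregate features across subjects and classify ICs
#'
#' Features are averaged over subjects per IC; an IC is signal iff all four
#' mean features are at or below their thresholds (boundary inclusive).
#'
#' @param features per-(subject, IC) table from [computeIcFeatures()].
#' @param thresholds a [qcThresholds()].
#' @return per-IC data.frame with the mean features and a logical `signal`
#'   column.
#' @export
aggregateAndClassify <- function(features, thresholds = qcThresholds()) {
  need <- c("subject", "ic", "edgeFraction", "csfFraction",
            "maxRpCorr", "hfContent")
  stopifnot(all(need %in% names(features)))
  if (anyNA(features[need])) stop("missing feature cells: cannot aggregate")
  counts <- table(features$ic)
  if (length(unique(counts)) != 1)
    stop("missing (subject, IC) cells: cannot aggregate")
  agg <- stats::aggregate(
    features[c("edgeFraction", "csfFraction", "maxRpCorr", "hfContent")],
    by = list(ic = features$ic), FUN = mean)
  agg <- agg[order(match(agg$ic, unique(features$ic))), ]
  agg$signal <- agg$maxRpCorr <= thresholds$maxRpCorr &
    agg$hfContent <= thresholds$hfContent &
    agg$edgeFraction <= thresholds$edgeFraction &
    agg$csfFraction <= thresholds$csfFraction
  rownames(agg) <- NULL
  agg
}

#' Trilinear / nearest-neighbour volume resampling
#'
#' @param vol 3-d array.
#' @param newDim integer(3) target grid.
#' @param method "linear" or "nearest".
#' @return resampled array of dimension `newDim`.
#' @export
resampleVolume <- function(vol, newDim, method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- dim(vol)
  newDim <- as.integer(newDim)
  coord <- lapply(1:3, function(a)
    (seq_len(newDim[a]) - 0.5) * d[a] / newDim[a] + 0.5)
  if (method == "nearest") {
    ix <- pmin(pmax(round(coord[[1]]), 1L), d[1])
    iy <- pmin(pmax(round(coord[[2]]), 1L), d[2])
    iz <- pmin(pmax(round(coord[[3]]), 1L), d[3])
    return(vol[ix, iy, iz, drop = FALSE])
  }
  lo <- lapply(1:3, function(a) pmin(pmax(floor(coord[[a]]), 1L), d[a]))
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, d[a]))
  fr <- lapply(1:3, function(a)
    pmin(pmax(coord[[a]] - lo[[a]], 0), 1))
  out <- array(0, dim = newDim)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (cz == 0) 1 - fr[[3]] else fr[[3]]
    ix <- if (cx == 0) lo[[1]] else hi[[1]]
    iy <- if (cy == 0) lo[[2]] else hi[[2]]
    iz <- if (cz == 0) lo[[3]] else hi[[3]]
    w <- outer(outer(wx, wy), wz)
    out <- out + w * vol[ix, iy, iz, drop = FALSE]
  }
  out
}

#' Assign ICs to reference networks by spatial correlation
#'
#' Each IC map is Pearson-correlated with every labelled reference map over
#' the in-brain voxels; the IC gets the label of the best-correlating
#' reference, or "unassigned" when the maximum correlation does not exceed
#' `minCorr`. Ties are broken towards the lowest reference index (logged).
#'
#' @param icMaps a [SpatialMapSet-class].
#' @param referenceMaps a labelled [SpatialMapSet-class]; if its grid differs
#'   it is resampled (linear) to the IC grid first.
#' @param minCorr assignment threshold (default 0.20).
#' @param mask optional binary volume restricting the correlation support
#'   (e.g. the brain mask).
#' @return data.frame with columns `ic`, `label`, `correlation`.
#' @export
assignNetworks <- function(icMaps, referenceMaps, minCorr = 0.20,
                           mask = NULL) {
  g <- gridDim(icMaps)
  refs <- referenceMaps@maps
  if (!identical(unname(gridDim(referenceMaps)), unname(g))) {
    refs <- array(0, dim = c(g, nMaps(referenceMaps)))
    for (k in seq_len(nMaps(referenceMaps)))
      refs[, , , k] <- resampleVolume(icMap(referenceMaps, k), g, "linear")
  }
  sel <- if (is.null(mask)) rep(TRUE, prod(g)) else as.vector(mask == 1)
  refMat <- matrix(refs, ncol = dim(refs)[4])[sel, , drop = FALSE]
  keep <- apply(refMat, 2, stats::sd) > 0
  if (!all(keep))
    warning("zero-variance reference map(s) skipped: ",
            paste(icIds(referenceMaps)[!keep], collapse = ", "))
  refMat <- refMat[, keep, drop = FALSE]
  labs <- icIds(referenceMaps)[keep]
  icMat <- matrix(icMaps@maps, ncol = nMaps(icMaps))[sel, , drop = FALSE]
  out <- data.frame(ic = icIds(icMaps), label = NA_character_,
                    correlation = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(icMat))) {
    r <- as.numeric(stats::cor(icMat[, k], refMat))
    best <- which(r == max(r))
    if (length(best) > 1) {
      message("IC ", out$ic[k], ": spatial-correlation tie broken towards ",
              labs[best[1]])
      best <- best[1]
    }
    out$correlation[k] <- r[best]
    out$label[k] <- if (r[best] > minCorr) labs[best] else "unassigned"
  }
  out
}
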