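## Temporal side of the synthetic cohort. Node series are multivariate normal
## with a per-subject correlation matrix (population planted edges + Gaussian
## subject deviation on the Fisher-z scale), low-pass filtered with one shared
## Gaussian kernel so signal ICs have BOLD-like spectra. A common linear
## filter leaves the instantaneous correlations of stationary Gaussian series
## unchanged, so planted edge strengths survive the smoothing.

gaussKernel <- function(sigma) {
  h <- ceiling(4 * sigma)
  k <- exp(-((-h):h)^2 / (2 * sigma^2))
  k / sum(k)
}

## circular convolution smoothing of each column (keeps length, stationary)
lowpassColumns <- function(X, sigma) {
  if (sigma <= 0) return(X)
  k <- gaussKernel(sigma)
  apply(X, 2, function(col)
    as.numeric(stats::filter(col, k, method = "convolution",
                             sides = 2, circular = TRUE)))
}

## per-subject correlation matrix: population planted edges jittered on the
## z-scale; repaired to the nearest PD correlation matrix when needed
subjectCorrMatrix <- function(config) {
  n <- config$nNodes
  P <- diag(1, n)
  pe <- config$plantedEdges
  if (nrow(pe)) {
    pr <- edgeToPair(pe$edge, n)
    for (k in seq_len(nrow(pe))) {
      P[pr$i[k], pr$j[k]] <- P[pr$j[k], pr$i[k]] <- pe$popR[k]
    }
  }
  z <- atanh(P * 0.999999)
  dev <- matrix(0, n, n)
  dev[upper.tri(dev)] <- stats::rnorm(n * (n - 1) / 2, 0, config$subjectSd)
  dev <- dev + t(dev)
  Ps <- tanh(z + dev)
  diag(Ps) <- 1
  ev <- eigen(Ps, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    message("requested correlation matrix not positive definite; ",
            "repaired by nearest-PD projection")
    Ps <- as.matrix(Matrix::nearPD(Ps, corr = TRUE)$mat)
  }
  Ps
}

#' Generate per-subject node time series and realignment parameters
#'
#' Each subject's T x N series is multivariate normal with a subject-specific
#' correlation matrix carrying the planted population edge strengths plus an
#' independent Gaussian subject deviation (sd `config$subjectSd` on the
#' Fisher-z scale). Signal columns are low-pass filtered (Gaussian kernel, sd
#' `config$lowpassSigma` samples) so their high-frequency content sits well
#' below the 0.3 quality-control threshold; designated high-frequency-noise
#' ICs stay white (HF content ~0.86 at TR = 0.72 s); designated RP-noise ICs
#' are mixed with one realignment-parameter series (weight `config$rpMix`)
#' so their maximum RP correlation exceeds 0.5. Six realignment-parameter
#' series are generated per subject as smooth AR(1) drifts.
#'
#' @param config a [syntheticConfig()].
#' @param truth the `GroundTruth` from [genSpatialMaps()] (for noise types).
#' @return list with `ts` (list of [NodeTimeSeries-class]) and `rp` (list of
#'   T x 6 realignment-parameter matrices).
#' @export
genTimeseries <- function(config, truth) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed + 2L)
  nT <- config$nTimepoints
  n <- config$nNodes
  hfIcs <- which(truth$noiseType == "hf")
  rpIcs <- which(truth$noiseType == "rp")
  tsList <- vector("list", config$nSubjects)
  rpList <- vector("list", config$nSubjects)
  for (s in seq_len(config$nSubjects)) {
    Ps <- subjectCorrMatrix(config)
    X <- matrix(stats::rnorm(nT * n), nT, n) %*% chol(Ps)
    smooth <- lowpassColumns(X, config$lowpassSigma)
    smooth[, hfIcs] <- X[, hfIcs]               # HF-noise ICs stay white
    X <- smooth
    rp <- vapply(1:6, function(k) {
      as.numeric(stats::arima.sim(list(ar = 0.95), nT))
    }, numeric(nT))
    for (m in seq_along(rpIcs)) {
      k <- rpIcs[m]
      col <- ((m - 1L) %% 6L) + 1L
      a <- config$rpMix
      X[, k] <- a * scale(rp[, col])[, 1] + sqrt(1 - a^2) * scale(X[, k])[, 1]
    }
    colnames(X) <- paste0("node", seq_len(n))
    tsList[[s]] <- new("NodeTimeSeries", subject = sprintf("sub%03d", s),
                       series = X, tr = config$tr)
    rpList[[s]] <- rp
  }
  list(ts = tsList, rp = rpList)
}

#' Generate a subjects x edges matrix with planted edge-score correlations
#'
#' Edge-level fast path used when only the selection stage is exercised: draws
#' a standard-normal chemosensory score and a subjects x edges matrix in which
#' each planted edge has the stated population correlation with the score and
#' all other edges are independent noise.
#'
#' @param nSubjects,nEdges matrix dimensions.
#' @param planted integer vector of planted edge indices.
#' @param plantedR population correlation between each planted edge and the
#'   score (recycled).
#' @param seed integer seed.
#' @return list with `edges` (matrix) and `score` (numeric vector).
#' @export
genEdgeMatrix <- function(nSubjects, nEdges, planted = integer(0),
                          plantedR = 0.3, seed = 1L) {
  stopifnot(all(planted >= 1), all(planted <= nEdges),
            all(abs(plantedR) < 1))
  set.seed(as.integer(seed))
  score <- stats::rnorm(nSubjects)
  edges <- matrix(stats::rnorm(nSubjects * nEdges), nSubjects, nEdges)
  r <- rep_len(plantedR, length(planted))
  for (k in seq_along(planted)) {
    edges[, planted[k]] <- r[k] * score +
      sqrt(1 - r[k]^2) * edges[, planted[k]]
  }
  colnames(edges) <- paste0("e", seq_len(nEdges))
  list(edges = edges, score = score)
}
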