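#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic cohort: dimensions, which ICs are
#' planted as noise (one designated quality-control violation each), which
#' connectome edges drive the chemosensory scores, and the linear models that
#' generate the alcohol outcomes. The defaults describe the package's standard
#' study conditions: 40 ICs of which 8 are noise (two per noise type), four
#' planted edges (two per chemosensory score) among signal nodes, and
#' HCP-style timing (TR = 0.72 s).
#'
#' @param seed integer; every generator call derives its random stream from
#'   this. Identical seed + config reproduces byte-identical outputs.
#' @param nSubjects,nNodes,nTimepoints cohort dimensions.
#' @param tr repetition time in seconds.
#' @param gridShape integer(3), voxel grid for maps and masks.
#' @param noiseIcs named list with integer vectors `edge`, `csf`, `rp`, `hf`:
#'   the ICs planted to violate, respectively, the edge-fraction,
#'   CSF-fraction, realignment-parameter-correlation and high-frequency
#'   thresholds.
#' @param plantedEdges data.frame with columns `edge` (index into the
#'   row-major upper-triangle edge vector over all `nNodes` nodes), `score`
#'   ("odor" or "taste"), `weight` (effect of the standardized edge value on
#'   the score) and `popR` (population correlation planted between the two
#'   nodes).
#' @param outcomeSpec list of outcome specifications, each a list with
#'   `name`, `intercept`, `edges` (named numeric, names = edge indices),
#'   `covariates` (named numeric over age, sex, bmi, ftnd), `sd` (noise sd)
#'   and `type` ("count" for non-negative rounded past-week counts,
#'   "rawYear" handled specially).
#' @param subjectSd sd of the per-subject edge-strength deviation on the
#'   Fisher-z scale (population edge value + subject deviation).
#' @param lowpassSigma sd, in samples, of the Gaussian low-pass kernel applied
#'   to signal node series so their spectral content is BOLD-like (mostly
#'   below 0.1 Hz); high-frequency-noise ICs are left unfiltered.
#' @param rpMix mixing weight of the realignment-parameter series into
#'   RP-noise IC time courses (gives max RP correlation near `rpMix`).
#' @param scoreNoiseSd sd of the Gaussian noise added to the chemosensory
#'   scores.
#' @param missingRate fraction of measurement cells set missing completely at
#'   random.
#'
#' @return an object of class `SyntheticConfig` (a validated list).
#' @export
syntheticConfig <- function(seed = 1L,
                            nSubjects = 20L,
                            nNodes = 40L,
                            nTimepoints = 600L,
                            tr = 0.72,
                            gridShape = c(14L, 14L, 14L),
                            noiseIcs = list(edge = c(33L, 34L),
                                            csf = c(35L, 36L),
                                            rp = c(37L, 38L),
                                            hf = c(39L, 40L)),
                            plantedEdges = NULL,
                            outcomeSpec = NULL,
                            subjectSd = 0.1,
                            lowpassSigma = 3,
                            rpMix = 0.75,
                            scoreNoiseSd = 0.5,
                            missingRate = 0.05) {
  seed <- as.integer(seed)
  nSubjects <- as.integer(nSubjects)
  nNodes <- as.integer(nNodes)
  nTimepoints <- as.integer(nTimepoints)
  gridShape <- as.integer(gridShape)
  stopifnot(nSubjects >= 1, nNodes >= 2, length(gridShape) == 3,
            all(gridShape > 0), tr > 0,
            missingRate >= 0, missingRate <= 1)
  if (nTimepoints < 64)
    stop("nTimepoints must be >= 64 (spectral estimation needs segments)")
  noiseIcs <- lapply(noiseIcs, as.integer)
  allNoise <- unlist(noiseIcs, use.names = FALSE)
  if (anyDuplicated(allNoise))
    stop("an IC may carry only one designated noise type")
  if (length(allNoise) && (min(allNoise) < 1 || max(allNoise) > nNodes))
    stop("noise IC indices out of range")
  if (is.null(plantedEdges)) {
    if (nNodes < 8) stop("default plantedEdges need nNodes >= 8")
    plantedEdges <- data.frame(
      edge = c(pairToEdge(1L, 2L, nNodes), pairToEdge(3L, 4L, nNodes),
               pairToEdge(5L, 6L, nNodes), pairToEdge(7L, 8L, nNodes)),
      score = c("odor", "odor", "taste", "taste"),
      weight = c(1.0, 0.8, 1.0, 0.8),
      popR = 0.3,
      stringsAsFactors = FALSE)
  }
  nEdges <- nNodes * (nNodes - 1L) / 2L
  if (nrow(plantedEdges) &&
      (min(plantedEdges$edge) < 1 || max(plantedEdges$edge) > nEdges))
    stop("planted edge indices must lie in 1..nNodes*(nNodes-1)/2")
  signalSet <- setdiff(seq_len(nNodes), allNoise)
  if (nrow(plantedEdges)) {
    pairs <- edgeToPair(plantedEdges$edge, nNodes)
    if (!all(pairs$i %in% signalSet & pairs$j %in% signalSet))
      stop("every planted edge must connect two non-noise ICs")
  }
  if (is.null(outcomeSpec)) {
    if (!nrow(plantedEdges)) stop("default outcomeSpec needs planted edges")
    eo <- as.character(plantedEdges$edge[plantedEdges$score == "odor"])
    et <- as.character(plantedEdges$edge[plantedEdges$score == "taste"])
    if (!length(eo)) eo <- as.character(plantedEdges$edge[1])
    if (!length(et)) et <- as.character(plantedEdges$edge[1])
    e <- c(eo[1], eo[1], et[1], et[1])
    outcomeSpec <- list(
      list(name = "totalDrinks7", intercept = 8, type = "count",
           edges = stats::setNames(c(1.5, 1.0), e[c(1, 3)]),
           covariates = c(age = 0.05, sex = 1.0, bmi = 0.05, ftnd = 0.5),
           sd = 2),
      list(name = "wine7", intercept = 3, type = "count",
           edges = stats::setNames(1.2, e[1]),
           covariates = c(age = 0.02, sex = -0.3, bmi = 0, ftnd = 0),
           sd = 1),
      list(name = "beerWineCooler7", intercept = 4, type = "count",
           edges = stats::setNames(1.0, e[3]),
           covariates = c(age = 0, sex = 0.8, bmi = 0.02, ftnd = 0.3),
           sd = 1.5),
      list(name = "drinksPerDayRaw", intercept = 2.5, type = "rawYear",
           edges = stats::setNames(0.8, e[1]),
           covariates = c(age = 0, sex = 0.5, bmi = 0, ftnd = 0.4),
           sd = 1),
      list(name = "maxDrinksRaw", intercept = 5, type = "rawYear",
           edges = stats::setNames(1.0, e[3]),
           covariates = c(age = 0, sex = 1.5, bmi = 0, ftnd = 0.5),
           sd = 2))
  }
  cfg <- list(seed = seed, nSubjects = nSubjects, nNodes = nNodes,
              nTimepoints = nTimepoints, tr = tr, gridShape = gridShape,
              noiseIcs = noiseIcs, plantedEdges = plantedEdges,
              outcomeSpec = outcomeSpec, subjectSd = subjectSd,
              lowpassSigma = lowpassSigma, rpMix = rpMix,
              scoreNoiseSd = scoreNoiseSd, missingRate = missingRate)
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' @export
print.SyntheticConfig <- function(x, ...) {
  cat(sprintf(
    "SyntheticConfig: %d subjects, %d nodes (%d noise ICs), T = %d, TR = %.3g s\n",
    x$nSubjects, x$nNodes, length(unlist(x$noiseIcs)), x$nTimepoints, x$tr))
  cat(sprintf("  %d planted edges, %d outcomes, seed %d\n",
              nrow(x$plantedEdges), length(x$outcomeSpec), x$seed))
  invisible(x)
}

#' Ground truth planted by the generator
#'
#' @param x a `GroundTruth` object (list with `noiseType` per IC — "signal",
#'   "edge", "csf", "rp" or "hf" —, logical `noiseFlags`, the planted edge
#'   table, the true outcome coefficient list and `networkLabel` per IC).
#' @name GroundTruth
NULL

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth: %d ICs (%d noise), %d planted edges\n",
              length(x$noiseFlags), sum(x$noiseFlags), nrow(x$plantedEdges)))
  invisible(x)
}
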