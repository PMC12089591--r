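## Phenotype side of the synthetic cohort: chemosensory scores are noisy
## linear functions of the planted (standardized) edge values; alcohol
## outcomes follow the configured linear models over edges and covariates;
## covariate distributions are simple stand-ins whose only job is to act as
## confounders (age uniform over the HCP young-adult range, sex Bernoulli,
## BMI log-normal, FTND Poisson).

zcol <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Generate the subject phenotype table
#'
#' @param config a [syntheticConfig()].
#' @param edgeMat subjects x E numeric matrix of edge values vectorized over
#'   all `config$nNodes` nodes (columns indexed as in [edgeIndexMap()]), as
#'   produced by [edgeMatrix()] on the full connectomes.
#' @param truth the `GroundTruth` from [genSpatialMaps()].
#' @return a `data.frame` (SubjectTable) with columns `subject`, covariates
#'   (`age`, `sex` with 1 = male, `bmi`, `ftnd`), chemosensory scores
#'   (`odor`, `taste`), past-week counts (`totalDrinks7`, `wine7`,
#'   `beerWineCooler7`, `maltLiquor7`, `hardLiquor7`, `other7`), past-year raw
#'   quantities (`drinksPerDayRaw`, `maxDrinksRaw`) and their recoded
#'   categories (`drinksPerDayCode`, `maxDrinksCode`). Cells of measurement
#'   columns are set missing completely at random at `config$missingRate`;
#'   an attribute `missingMask` records which cells were blanked.
#' @export
genPhenotypes <- function(config, edgeMat, truth) {
  stopifnot(inherits(config, "SyntheticConfig"))
  nS <- nrow(edgeMat)
  nEdges <- config$nNodes * (config$nNodes - 1) / 2
  if (ncol(edgeMat) != nEdges)
    stop("edgeMat must have nNodes*(nNodes-1)/2 columns (all-node edges)")
  set.seed(config$seed + 3L)

  age <- stats::runif(nS, 22, 37)
  sex <- stats::rbinom(nS, 1, 0.5)
  bmi <- stats::rlnorm(nS, log(25), 0.15)
  ftnd <- stats::rpois(nS, 1)
  cov <- cbind(age = age, sex = sex, bmi = bmi, ftnd = ftnd)

  pe <- truth$plantedEdges
  score <- function(which) {
    rows <- pe[pe$score == which, , drop = FALSE]
    base <- 0
    for (k in seq_len(nrow(rows)))
      base <- base + rows$weight[k] * zcol(edgeMat[, rows$edge[k]])
    base + stats::rnorm(nS, 0, config$scoreNoiseSd)
  }
  odor <- score("odor")
  taste <- score("taste")

  tab <- data.frame(subject = sprintf("sub%03d", seq_len(nS)),
                    age = age, sex = sex, bmi = bmi, ftnd = ftnd,
                    odor = odor, taste = taste,
                    stringsAsFactors = FALSE)
  if (!is.null(rownames(edgeMat))) tab$subject <- rownames(edgeMat)

  specNames <- vapply(config$outcomeSpec, `[[`, character(1), "name")
  for (spec in config$outcomeSpec) {
    eIdx <- as.integer(names(spec$edges))
    if (length(eIdx) && (anyNA(eIdx) || any(eIdx < 1) || any(eIdx > nEdges)))
      stop("outcome '", spec$name, "' references an unknown edge")
    if (!all(names(spec$covariates) %in% colnames(cov)))
      stop("outcome '", spec$name, "' references an unknown covariate")
    y <- spec$intercept + stats::rnorm(nS, 0, spec$sd)
    for (k in seq_along(eIdx))
      y <- y + spec$edges[k] * zcol(edgeMat[, eIdx[k]])
    for (nm in names(spec$covariates))
      y <- y + spec$covariates[[nm]] * cov[, nm]
    tab[[spec$name]] <- switch(spec$type,
      count = pmax(0, round(y)),
      rawYear = if (spec$name == "maxDrinksRaw") pmax(1, round(y))
                else pmax(0, round(y)),
      y)
  }
  # past-week variables not driven by planted edges: background drinking noise
  for (nm in setdiff(c("totalDrinks7", "wine7", "beerWineCooler7",
                       "maltLiquor7", "hardLiquor7", "other7"), specNames))
    tab[[nm]] <- stats::rpois(nS, 1)
  if (!"drinksPerDayRaw" %in% specNames)
    tab$drinksPerDayRaw <- stats::rpois(nS, 2)
  if (!"maxDrinksRaw" %in% specNames)
    tab$maxDrinksRaw <- 1 + stats::rpois(nS, 3)

  tab$drinksPerDayCode <- recodeDrinksPerDay(tab$drinksPerDayRaw)
  tab$maxDrinksCode <- recodeMaxDrinks(tab$maxDrinksRaw, tab$sex)

  measureCols <- setdiff(names(tab),
                         c("subject", "age", "sex",
                           "drinksPerDayCode", "maxDrinksCode"))
  mask <- matrix(FALSE, nS, length(measureCols),
                 dimnames = list(NULL, measureCols))
  if (config$missingRate > 0) {
    for (cn in measureCols) {
      hit <- stats::runif(nS) < config$missingRate
      tab[[cn]][hit] <- NA
      mask[, cn] <- hit
    }
    tab$drinksPerDayCode[is.na(tab$drinksPerDayRaw)] <- NA
    tab$maxDrinksCode[is.na(tab$maxDrinksRaw)] <- NA
  }
  attr(tab, "missingMask") <- mask
  tab
}
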