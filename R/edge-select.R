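#' Edge-selection configuration
#'
#' Parameters of the leave-one-out edge-selection rule: an optional full-sample
#' prefilter (P < 0.001), the per-iteration significance level (P < 0.05 in
#' every leave-one-out iteration) and the FDR level of the Benjamini-Hochberg
#' step applied to the averaged leave-one-out p-values.
#'
#' @param prefilterAlpha full-sample p threshold for the prefilter.
#' @param usePrefilter apply the full-sample prefilter as a conjunctive
#'   criterion (default TRUE).
#' @param iterAlpha per-iteration significance level.
#' @param fdrQ Benjamini-Hochberg FDR level.
#' @param score which chemosensory score the run targets ("odor" or "taste").
#' @param combine how the per-iteration p-values are combined before FDR
#'   ("mean", "median" or "fisher").
#' @return list of class `SelectionConfig`.
#' @export
selectionConfig <- function(prefilterAlpha = 0.001, usePrefilter = TRUE,
                            iterAlpha = 0.05, fdrQ = 0.05,
                            score = c("odor", "taste"),
                            combine = c("mean", "median", "fisher")) {
  stopifnot(prefilterAlpha > 0, prefilterAlpha < 1,
            iterAlpha > 0, iterAlpha < 1, fdrQ > 0, fdrQ < 1)
  cfg <- list(prefilterAlpha = prefilterAlpha, usePrefilter = usePrefilter,
              iterAlpha = iterAlpha, fdrQ = fdrQ,
              score = match.arg(score), combine = match.arg(combine))
  class(cfg) <- "SelectionConfig"
  cfg
}

## vectorized Pearson r of each column of X with y, plus two-sided p from the
## t-distribution with n-2 df; zero-variance columns get r = 0, p = 1
corWithP <- function(X, y) {
  n <- length(y)
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  sx <- sqrt(colSums(Xc^2))
  sy <- sqrt(sum(yc^2))
  bad <- sx == 0 | sy == 0
  r <- rep(0, ncol(X))
  ok <- !bad
  if (sy > 0) r[ok] <- as.numeric(crossprod(Xc[, ok, drop = FALSE], yc)) /
      (sx[ok] * sy)
  r <- pmin(1, pmax(-1, r))
  p <- rep(1, ncol(X))
  df <- n - 2
  tt <- abs(r[ok]) * sqrt(df / pmax(1 - r[ok]^2, 1e-300))
  p[ok] <- 2 * stats::pt(tt, df, lower.tail = FALSE)
  if (any(bad)) warning("zero-variance edge or score: r = 0, p = 1 assigned")
  list(r = r, p = p)
}

#' Edge-wise correlation with a chemosensory score
#'
#' Pearson r and two-sided p (t-distribution, S - 2 df) of every edge column
#' against the score vector.
#'
#' @param edges subjects x E numeric matrix (no missing entries; imputation
#'   happens upstream).
#' @param scores numeric vector, length >= 4.
#' @return data.frame with columns `edge`, `r`, `p`.
#' @export
edgewiseCorrelation <- function(edges, scores) {
  edges <- as.matrix(edges)
  if (nrow(edges) != length(scores)) stop("edges and scores differ in length")
  if (length(scores) < 4) stop("need at least 4 subjects")
  if (anyNA(edges) || anyNA(scores)) stop("missing entries: impute upstream")
  cp <- corWithP(edges, scores)
  data.frame(edge = seq_len(ncol(edges)), r = cp$r, p = cp$p)
}

#' Leave-one-out p-value matrix
#'
#' Row s holds the edge-wise two-sided p-values computed with subject s
#' excluded. The per-iteration correlations are obtained by downdating the
#' sufficient statistics (computed on mean-centred data for numerical
#' stability), so the whole matrix costs O(S x E) rather than O(S^2 x E).
#'
#' @inheritParams edgewiseCorrelation
#' @return S x E matrix of p-values.
#' @export
loocvPvalues <- function(edges, scores) {
  edges <- as.matrix(edges)
  S <- nrow(edges)
  if (S < 5) stop("need at least 5 subjects for leave-one-out")
  if (anyNA(edges) || anyNA(scores)) stop("missing entries: impute upstream")
  Xc <- sweep(edges, 2, colMeans(edges))
  yc <- scores - mean(scores)
  Sx <- colSums(Xc); Sxx <- colSums(Xc^2); Sxy <- as.numeric(crossprod(Xc, yc))
  Sy <- sum(yc); Syy <- sum(yc^2)
  out <- matrix(NA_real_, S, ncol(edges))
  df <- S - 3                                # (S - 1) subjects, minus 2
  for (s in seq_len(S)) {
    n1 <- S - 1
    sx <- Sx - Xc[s, ]; sxx <- Sxx - Xc[s, ]^2; sxy <- Sxy - Xc[s, ] * yc[s]
    sy <- Sy - yc[s]; syy <- Syy - yc[s]^2
    vx <- pmax(sxx - sx^2 / n1, 0)
    vy <- max(syy - sy^2 / n1, 0)
    cv <- sxy - sx * sy / n1
    denom <- sqrt(vx * vy)
    r <- ifelse(denom > 0, cv / denom, 0)
    r <- pmin(1, pmax(-1, r))
    tt <- abs(r) * sqrt(df / pmax(1 - r^2, 1e-300))
    p <- 2 * stats::pt(tt, df, lower.tail = FALSE)
    p[denom == 0] <- 1
    out[s, ] <- p
  }
  rownames(out) <- rownames(edges)
  colnames(out) <- colnames(edges)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1); an edge is rejected
#' when its adjusted value is strictly below `q`.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param q FDR level.
#' @return list with `adjusted` and logical `reject`.
#' @export
bhFdr <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) return(list(adjusted = numeric(0),
                                    reject = logical(0)))
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adj, reject = adj < q)
}

#' Holm-Bonferroni adjustment
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return step-down adjusted p-values.
#' @export
holmAdjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "holm")
}

combinePvalues <- function(loocvP, how) {
  switch(how,
    mean = colMeans(loocvP),
    median = apply(loocvP, 2, stats::median),
    fisher = {
      stat <- -2 * colSums(log(pmax(loocvP, 1e-300)))
      stats::pchisq(stat, df = 2 * nrow(loocvP), lower.tail = FALSE)
    })
}

#' Select chemosensory-associated edges
#'
#' Combines the three criteria of the selection rule: (i) optional full-sample
#' prefilter at P < `prefilterAlpha`; (ii) Benjamini-Hochberg FDR on the
#' averaged leave-one-out p-values across all edges at level `fdrQ`; (iii) the
#' every-iteration rule (p < `iterAlpha` in each leave-one-out iteration). An
#' edge is selected only if it passes all enabled criteria; its correlation
#' sign comes from the full-sample r.
#'
#' @param loocvP S x E p-value matrix from [loocvPvalues()].
#' @param fullStats full-sample per-edge statistics from
#'   [edgewiseCorrelation()].
#' @param cfg a [selectionConfig()].
#' @return data.frame (one row per edge) with `edge`, `r`, `p`, `meanP`, `q`,
#'   `iterFrac` (fraction of iterations with p < `iterAlpha`), `sign`,
#'   `selected`. The edge name (if column names were present) is kept in
#'   `name`.
#' @export
selectEdges <- function(loocvP, fullStats, cfg = selectionConfig()) {
  if (ncol(loocvP) != nrow(fullStats))
    stop("loocvP and fullStats disagree on the number of edges")
  meanP <- combinePvalues(loocvP, cfg$combine)
  fdr <- bhFdr(meanP, cfg$fdrQ)
  iterFrac <- colMeans(loocvP < cfg$iterAlpha)
  selected <- fdr$reject & iterFrac == 1
  if (cfg$usePrefilter) selected <- selected & fullStats$p < cfg$prefilterAlpha
  out <- data.frame(edge = fullStats$edge,
                    r = fullStats$r, p = fullStats$p,
                    meanP = meanP, q = fdr$adjusted,
                    iterFrac = iterFrac,
                    sign = sign(fullStats$r),
                    selected = selected)
  if (!is.null(colnames(loocvP))) out$name <- colnames(loocvP)
  rownames(out) <- NULL
  out
}
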