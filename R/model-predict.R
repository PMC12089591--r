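#' Proximity-weighted k-nearest-neighbour imputation
#'
#' Each missing numeric cell is replaced by the proximity-weighted mean of the
#' k most similar subjects, where similarity derives from standardized
#' Euclidean distance over the columns both subjects have observed; proximity
#' weight is 1 / (1 + distance). Observed cells are never touched.
#'
#' @param table data.frame; non-numeric columns are passed through untouched.
#' @param k number of neighbours (default 10).
#' @param columns columns eligible for imputation (default: all numeric).
#' @return the completed data.frame, with a logical attribute `imputedMask`
#'   marking the cells that were filled.
#' @export
imputeProximity <- function(table, k = 10L, columns = NULL) {
  num <- vapply(table, is.numeric, logical(1))
  if (is.null(columns)) columns <- names(table)[num]
  stopifnot(all(columns %in% names(table)[num]))
  X <- as.matrix(table[columns])
  if (!anyNA(X)) {
    attr(table, "imputedMask") <- is.na(X) # all FALSE
    return(table)
  }
  allMissing <- rowSums(!is.na(X)) == 0
  if (any(allMissing)) {
    who <- if ("subject" %in% names(table))
      table$subject[allMissing] else which(allMissing)
    stop("subject(s) with all features missing: ",
         paste(who, collapse = ", "))
  }
  mu <- colMeans(X, na.rm = TRUE)
  sdv <- apply(X, 2, stats::sd, na.rm = TRUE)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  mask <- is.na(X)
  filled <- X
  for (i in which(rowSums(mask) > 0)) {
    shared <- sweep(Z, 2, Z[i, ], "-")^2
    obs <- !is.na(Z[i, ])
    d <- sqrt(rowMeans(shared[, obs, drop = FALSE], na.rm = TRUE))
    d[i] <- Inf
    for (j in which(mask[i, ])) {
      cand <- which(!mask[, j] & is.finite(d))
      if (!length(cand)) next
      nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      w <- 1 / (1 + d[nb])
      filled[i, j] <- sum(w * X[nb, j]) / sum(w)
    }
  }
  table[columns] <- as.data.frame(filled)
  attr(table, "imputedMask") <- mask
  table
}

#' Random 70:30 train/validation partition
#'
#' @param table subject table.
#' @param trainFraction training fraction (training size =
#'   `round(trainFraction * n)`).
#' @param seed integer seed making the partition reproducible.
#' @return factor of length n with levels "train" and "validation".
#' @export
splitTrainValidation <- function(table, trainFraction = 0.7, seed = 1L) {
  n <- nrow(table)
  if (n < 10) stop("need at least 10 subjects to partition")
  nTrain <- round(trainFraction * n)
  set.seed(as.integer(seed))
  lab <- rep("validation", n)
  lab[sample.int(n, nTrain)] <- "train"
  factor(lab, levels = c("train", "validation"))
}

#' Match validation subjects to the training sample on key scores
#'
#' Greedy nearest-neighbour caliper matching: a validation subject is retained
#' when its standardized key vector (scaled by the training sds) lies within
#' Euclidean distance `caliper` of some training subject's keys.
#'
#' @param validation,training data.frames holding the key columns (complete).
#' @param keys key column names (default odor and taste scores).
#' @param caliper distance bound, in training-sd units.
#' @return list with `matched` (the retained validation rows), `index`
#'   (their row positions in `validation`) and `balance` (Welch t per key
#'   between training and the matched subset).
#' @export
matchValidation <- function(validation, training,
                            keys = c("odor", "taste"), caliper = 0.25) {
  stopifnot(all(keys %in% names(validation)), all(keys %in% names(training)))
  KV <- as.matrix(validation[keys]); KT <- as.matrix(training[keys])
  if (anyNA(KV) || anyNA(KT)) stop("key columns must be complete")
  sdv <- apply(KT, 2, stats::sd)
  sdv[sdv == 0] <- 1
  ZV <- sweep(KV, 2, sdv, "/"); ZT <- sweep(KT, 2, sdv, "/")
  keep <- vapply(seq_len(nrow(ZV)), function(i) {
    d2 <- colSums((t(ZT) - ZV[i, ])^2)
    min(d2) <= caliper^2
  }, logical(1))
  if (!any(keep))
    stop("no validation subject matched within the caliper; ",
         "consider increasing it")
  matched <- validation[keep, , drop = FALSE]
  balance <- do.call(rbind, lapply(keys, function(kk) {
    tt <- stats::t.test(training[[kk]], matched[[kk]])
    data.frame(key = kk, t = unname(tt$statistic), p = tt$p.value)
  }))
  list(matched = matched, index = which(keep), balance = balance)
}

#' Recode past-year drinks per drinking day (SSAGA)
#'
#' Categories: 0-4 map to themselves, 5-6 to 5, 7 or more to 6.
#'
#' @param raw non-negative integer count(s).
#' @return integer category 0-6.
#' @export
recodeDrinksPerDay <- function(raw) {
  ok <- !is.na(raw)
  if (any(raw[ok] < 0)) stop("raw drink count must be non-negative")
  out <- rep(NA_integer_, length(raw))
  r <- raw[ok]
  out[ok] <- as.integer(ifelse(r >= 7, 6L, ifelse(r >= 5, 5L, r)))
  out
}

#' Recode past-year maximum drinks in a single day (SSAGA)
#'
#' Categories: 1-2 = 1; 3-4 = 2; 5-6 = 3; 7-8 = 4; 9-10 = 5; 11-12 = 6 for
#' males and 5 for females; 13 or more = 7 for males and 5 for females.
#'
#' @param raw integer count(s) >= 1 (the scale starts at 1-2).
#' @param sex "male"/"female", or numeric with 1 = male, 0 = female.
#' @return integer category 1-7 (capped at 5 for females from 11 up).
#' @export
recodeMaxDrinks <- function(raw, sex) {
  sex <- rep_len(sex, length(raw))
  male <- if (is.numeric(sex)) sex == 1 else tolower(as.character(sex)) == "male"
  ok <- !is.na(raw)
  if (any(raw[ok] < 1)) stop("raw maximum-drinks count must be >= 1")
  base <- function(r) ifelse(r >= 13, 7L, pmin(7L, (as.integer(r) + 1L) %/% 2L))
  out <- rep(NA_integer_, length(raw))
  out[ok] <- base(raw[ok])
  fem <- ok & !male & raw >= 11
  out[fem] <- 5L
  as.integer(out)
}

#' Fit a covariate-adjusted GLM for one alcohol outcome
#'
#' Ordinary least-squares Gaussian GLM of the outcome on all selected edges
#' jointly plus the confounder covariates; per-coefficient t-tests; Holm
#' adjustment across the edge coefficients within the model. A per-edge
#' single-predictor mode fits one model per edge (each still adjusted for the
#' covariates) and pools the edge coefficients.
#'
#' @param outcome outcome column name.
#' @param training training data.frame containing the outcome, the edge
#'   columns and the covariates.
#' @param edgeCols names of the selected edge predictor columns (may be
#'   empty: covariate-only model).
#' @param covariates covariate column names.
#' @param perEdge fit one single-edge model per edge instead of the joint
#'   model.
#' @param level confidence level for the intervals.
#' @return a [GlmFit-class].
#' @export
fitGlm <- function(outcome, training, edgeCols = character(0),
                   covariates = c("age", "sex", "bmi", "ftnd"),
                   perEdge = FALSE, level = 0.95) {
  stopifnot(outcome %in% names(training),
            all(edgeCols %in% names(training)),
            all(covariates %in% names(training)))
  oneFit <- function(edges) {
    preds <- c(edges, covariates)
    form <- stats::reformulate(if (length(preds)) preds else "1",
                               response = outcome)
    X <- stats::model.matrix(form, training)
    if (qr(X)$rank < ncol(X)) {
      q <- qr(X)
      drop <- colnames(X)[setdiff(seq_len(ncol(X)),
                                  q$pivot[seq_len(q$rank)])]
      stop("rank-deficient design; collinear columns: ",
           paste(drop, collapse = ", "))
    }
    if (nrow(X) <= ncol(X)) stop("need n > predictors + 1")
    stats::lm(form, data = training)
  }
  collect <- function(fit) {
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit, level = level)
    data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
               ciLow = ci[, 1], ciHigh = ci[, 2], p = sm[, 4],
               pHolm = NA_real_, stringsAsFactors = FALSE)
  }
  if (perEdge && length(edgeCols)) {
    tabs <- lapply(edgeCols, function(e) {
      fit <- oneFit(e)
      tb <- collect(fit)
      tb[tb$term == e, , drop = FALSE]
    })
    covFit <- oneFit(edgeCols[1])
    cf <- collect(covFit)
    cf <- cf[cf$term != edgeCols[1], , drop = FALSE]
    cf <- rbind(do.call(rbind, tabs), cf)
    sigma <- summary(covFit)$sigma
    nobs <- stats::nobs(covFit)
  } else {
    fit <- oneFit(edgeCols)
    cf <- collect(fit)
    sigma <- summary(fit)$sigma
    nobs <- stats::nobs(fit)
  }
  isEdge <- cf$term %in% edgeCols
  cf$pHolm[isEdge] <- holmAdjust(cf$p[isEdge])
  rownames(cf) <- NULL
  new("GlmFit", outcome = outcome, coefficients = cf,
      edgeTerms = edgeCols, covariates = covariates,
      sigma = sigma, nobs = as.numeric(nobs))
}

#' Apply a trained GLM to new rows
#'
#' Evaluates the linear predictor per row; no refitting.
#'
#' @param fit a [GlmFit-class].
#' @param table data.frame with all predictor columns present.
#' @return numeric vector of predictions.
#' @export
predictApply <- function(fit, table) {
  cf <- coefTable(fit)
  beta <- stats::setNames(cf$estimate, cf$term)
  terms <- setdiff(names(beta), "(Intercept)")
  miss <- setdiff(terms, names(table))
  if (length(miss))
    stop("missing predictor column(s): ", paste(miss, collapse = ", "))
  pred <- rep(if ("(Intercept)" %in% names(beta)) beta[["(Intercept)"]] else 0,
              nrow(table))
  for (tm in terms) pred <- pred + beta[[tm]] * table[[tm]]
  pred
}
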