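#' Regression accuracy metrics
#'
#' @param predicted,actual numeric vectors of equal length (n >= 1).
#' @return named numeric: `mse` (mean squared residual) and `rmse` (its
#'   square root).
#' @export
regressionMetrics <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  if (!length(actual)) stop("empty vectors")
  mse <- mean((predicted - actual)^2)
  c(mse = mse, rmse = sqrt(mse))
}

#' Median-split classification metrics
#'
#' Both the actual and the predicted values are dichotomized at the same
#' reference median (computed over all samples of the actual outcome,
#' training plus validation): above the median codes 1 ("higher"
#' consumption), at or below codes 0. Confusion counts and accuracy,
#' precision, recall and F1 are reported for the positive (higher
#' consumption) class; 0/0 ratios are defined as 0.
#'
#' @param predicted,actual numeric vectors of equal length.
#' @param referenceMedian the all-sample median of the actual outcome.
#' @return one-row data.frame with `median`, `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `precision`, `recall`, `f1`.
#' @export
medianSplitMetrics <- function(predicted, actual, referenceMedian) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  aPos <- actual > referenceMedian
  pPos <- predicted > referenceMedian
  tp <- sum(pPos & aPos); fp <- sum(pPos & !aPos)
  tn <- sum(!pPos & !aPos); fn <- sum(!pPos & aPos)
  ratio <- function(a, b) if (b == 0) 0 else a / b
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  data.frame(median = referenceMedian, tp = tp, fp = fp, tn = tn, fn = fn,
             accuracy = (tp + tn) / length(actual),
             precision = precision, recall = recall,
             f1 = if (precision + recall == 0) 0 else
               2 * precision * recall / (precision + recall))
}

#' Train/validation comparability tests
#'
#' Welch t-tests for the continuous variables (age, BMI, odor, taste),
#' Wilcoxon rank-sum for the non-normally distributed FTND score and a
#' chi-squared test for sex.
#'
#' @param train,validation data.frames sharing the compared columns.
#' @return data.frame with `variable`, `test`, `statistic`, `p`.
#' @export
groupCompare <- function(train, validation) {
  if (!nrow(train) || !nrow(validation)) stop("empty group")
  cols <- c("sex", "age", "bmi", "ftnd", "odor", "taste")
  stopifnot(all(cols %in% names(train)), all(cols %in% names(validation)))
  rows <- list()
  for (v in c("age", "bmi", "odor", "taste")) {
    tt <- stats::t.test(train[[v]], validation[[v]])
    rows[[v]] <- data.frame(variable = v, test = "welch",
                            statistic = unname(tt$statistic), p = tt$p.value)
  }
  wt <- suppressWarnings(stats::wilcox.test(train$ftnd, validation$ftnd))
  rows$ftnd <- data.frame(variable = "ftnd", test = "wilcoxon",
                          statistic = unname(wt$statistic), p = wt$p.value)
  counts <- rbind(table(factor(train$sex, levels = 0:1)),
                  table(factor(validation$sex, levels = 0:1)))
  ct <- suppressWarnings(stats::chisq.test(counts))
  rows$sex <- data.frame(variable = "sex", test = "chisq",
                         statistic = unname(ct$statistic), p = ct$p.value)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Direct chemosensory-alcohol correlation table
#'
#' Pearson r and two-sided p for every (odor, taste) x alcohol-variable pair
#' and for every past-week x past-year pair.
#'
#' @param table complete (post-imputation) subject table.
#' @param chemo chemosensory score columns.
#' @param pastWeek past-week alcohol count columns (those present are used).
#' @param pastYear past-year (recoded) columns (those present are used).
#' @return data.frame with `var1`, `var2`, `r`, `p`.
#' @export
chemosensoryAlcoholCorrelations <- function(table,
    chemo = c("odor", "taste"),
    pastWeek = c("totalDrinks7", "beerWineCooler7", "maltLiquor7", "wine7",
                 "hardLiquor7", "other7"),
    pastYear = c("drinksPerDayCode", "maxDrinksCode")) {
  pastWeek <- intersect(pastWeek, names(table))
  pastYear <- intersect(pastYear, names(table))
  stopifnot(all(chemo %in% names(table)))
  pairs <- rbind(expand.grid(var1 = chemo,
                             var2 = c(pastWeek, pastYear),
                             stringsAsFactors = FALSE),
                 expand.grid(var1 = pastWeek, var2 = pastYear,
                             stringsAsFactors = FALSE))
  one <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("constant column: r = 0, p = 1 assigned")
      return(c(r = 0, p = 1))
    }
    ct <- stats::cor.test(x, y)
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  res <- t(vapply(seq_len(nrow(pairs)), function(k)
    one(table[[pairs$var1[k]]], table[[pairs$var2[k]]]), numeric(2)))
  data.frame(pairs, r = res[, 1], p = res[, 2])
}
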