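test_that("proximity imputation fills only missing cells, from neighbours", {
  set.seed(41)
  n <- 40
  x <- stats::rnorm(n)
  tab <- data.frame(subject = sprintf("s%02d", 1:n),
                    a = x, b = 2 * x + stats::rnorm(n, 0, 0.01),
                    c = stats::rnorm(n))
  ## complete table passes through untouched
  same <- imputeProximity(tab)
  expect_identical(same[names(tab)], tab[names(tab)])
  expect_false(any(attr(same, "imputedMask")))
  ## an exact duplicate at distance zero dominates with k = 1
  twin <- tab
  twin[2, c("a", "c")] <- twin[1, c("a", "c")]
  twin$b[2] <- NA
  out <- imputeProximity(twin, k = 1)
  expect_equal(out$b[2], twin$b[1])
  expect_true(attr(out, "imputedMask")[2, "b"])
  expect_equal(sum(attr(out, "imputedMask")), 1)
  ## observed cells are never modified
  expect_identical(out$a, twin$a)
  ## MCAR mask-and-recover: correlated columns make imputation beat the mean
  big <- tab
  hit <- sample(n, 8)
  big$b[hit] <- NA
  rec <- imputeProximity(big, k = 10)
  err <- rec$b[hit] - tab$b[hit]
  expect_lt(sqrt(mean(err^2)), stats::sd(tab$b))
  ## a subject with every feature missing is unrecoverable and named
  allNa <- tab
  allNa[5, c("a", "b", "c")] <- NA
  expect_error(imputeProximity(allNa), "s05")
})

test_that("the train/validation split has the documented sizes", {
  tab <- data.frame(x = seq_len(1003))
  part <- splitTrainValidation(tab, 0.7, seed = 1)
  expect_equal(sum(part == "train"), 702)
  expect_equal(sum(part == "validation"), 301)
  expect_equal(levels(part), c("train", "validation"))
  small <- splitTrainValidation(data.frame(x = 1:10), 0.7, seed = 1)
  expect_equal(sum(small == "train"), 7)
  ## deterministic in the seed, sensitive to it
  expect_identical(part, splitTrainValidation(tab, 0.7, seed = 1))
  expect_false(identical(part, splitTrainValidation(tab, 0.7, seed = 2)))
  expect_error(splitTrainValidation(data.frame(x = 1:5)), "at least 10")
})

test_that("caliper matching retains close subjects and balances keys", {
  mk <- function(n, shift = 0) data.frame(odor = stats::rnorm(n) + shift,
                                          taste = stats::rnorm(n) + shift)
  ## a validation row identical to a training row sits at distance 0
  set.seed(42)
  tr <- mk(300)
  va <- rbind(tr[7, ], mk(50))
  m <- matchValidation(va, tr, caliper = 0.25)
  expect_true(1 %in% m$index)
  expect_equal(nrow(m$matched), length(m$index))
  expect_equal(m$balance$key, c("odor", "taste"))
  ## same-distribution samples stay balanced after matching in most seeds
  balanced <- vapply(1:20, function(s) {
    set.seed(s)
    tr <- mk(300)
    va <- mk(100)
    all(matchValidation(va, tr, caliper = 0.25)$balance$p > 0.05)
  }, logical(1))
  expect_gte(sum(balanced), 12)
  ## far-away validation subjects cannot match
  set.seed(43)
  expect_error(matchValidation(mk(20, shift = 100), mk(50), caliper = 0.25),
               "caliper")
})

test_that("SSAGA recoding follows the category schemes", {
  expect_equal(recodeDrinksPerDay(0:10), c(0:4, 5, 5, 6, 6, 6, 6))
  expect_error(recodeDrinksPerDay(-1), "non-negative")
  expect_equal(recodeDrinksPerDay(c(2, NA)), c(2L, NA))
  expect_equal(recodeMaxDrinks(1:14, "male"),
               c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7))
  expect_equal(recodeMaxDrinks(1:14, "female"),
               c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 5, 5, 5, 5))
  ## numeric sex coding (1 = male) agrees with the string coding
  expect_equal(recodeMaxDrinks(1:14, 1), recodeMaxDrinks(1:14, "male"))
  expect_equal(recodeMaxDrinks(1:14, 0), recodeMaxDrinks(1:14, "female"))
  expect_error(recodeMaxDrinks(0, "male"), ">= 1")
  ## both schemes are monotone non-decreasing in the raw count
  expect_true(all(diff(recodeDrinksPerDay(0:30)) >= 0))
  expect_true(all(diff(recodeMaxDrinks(1:30, "male")) >= 0))
  expect_true(all(diff(recodeMaxDrinks(1:30, "female")) >= 0))
})

test_that("the GLM matches stats::lm coefficient by coefficient", {
  set.seed(44)
  n <- 80
  tab <- data.frame(age = stats::runif(n, 22, 37),
                    sex = stats::rbinom(n, 1, 0.5),
                    bmi = stats::rnorm(n, 25, 3),
                    ftnd = stats::rpois(n, 1),
                    edge1 = stats::rnorm(n), edge2 = stats::rnorm(n))
  tab$y <- 2 + 0.5 * tab$edge1 - 0.3 * tab$edge2 + 0.1 * tab$age +
    stats::rnorm(n)
  fit <- fitGlm("y", tab, edgeCols = c("edge1", "edge2"))
  ref <- stats::lm(y ~ edge1 + edge2 + age + sex + bmi + ftnd, tab)
  cf <- coefTable(fit)
  sm <- summary(ref)$coefficients
  ci <- stats::confint(ref)
  idx <- match(cf$term, rownames(sm))
  expect_equal(cf$estimate, unname(sm[idx, 1]), tolerance = 1e-10)
  expect_equal(cf$se, unname(sm[idx, 2]), tolerance = 1e-10)
  expect_equal(cf$p, unname(sm[idx, 4]), tolerance = 1e-10)
  expect_equal(cf$ciLow, unname(ci[idx, 1]), tolerance = 1e-10)
  expect_equal(cf$ciHigh, unname(ci[idx, 2]), tolerance = 1e-10)
  ## Holm is applied to the edge terms only
  isEdge <- cf$term %in% c("edge1", "edge2")
  expect_equal(cf$pHolm[isEdge], bruteHolm(cf$p[isEdge]), tolerance = 1e-12)
  expect_true(all(is.na(cf$pHolm[!isEdge])))
  ## noiseless data are recovered exactly
  tab$y0 <- 1 + 2 * tab$edge1 + 0.5 * tab$age
  ## a perfect fit makes summary.lm warn about unreliable inference;
  ## only the point estimate is asserted here
  fit0 <- suppressWarnings(
    fitGlm("y0", tab, edgeCols = "edge1", covariates = "age"))
  cf0 <- coefTable(fit0)
  expect_equal(cf0$estimate[cf0$term == "edge1"], 2, tolerance = 1e-8)
  ## collinear designs are refused with the offending column named
  tab$edge3 <- tab$edge1
  expect_error(fitGlm("y", tab, edgeCols = c("edge1", "edge3")), "edge3")
  expect_error(fitGlm("y", tab[1:7, ], edgeCols = c("edge1", "edge2")),
               "predictors")
})

test_that("per-edge fits agree with single-edge adjusted models", {
  set.seed(45)
  n <- 60
  tab <- data.frame(age = stats::rnorm(n, 30), sex = stats::rbinom(n, 1, .5),
                    bmi = stats::rnorm(n, 25), ftnd = stats::rpois(n, 1),
                    e1 = stats::rnorm(n), e2 = stats::rnorm(n))
  tab$y <- 1 + 0.4 * tab$e1 + stats::rnorm(n)
  fit <- fitGlm("y", tab, edgeCols = c("e1", "e2"), perEdge = TRUE)
  cf <- coefTable(fit)
  for (e in c("e1", "e2")) {
    ref <- stats::lm(stats::reformulate(c(e, "age", "sex", "bmi", "ftnd"),
                                        "y"), tab)
    expect_equal(cf$estimate[cf$term == e], unname(stats::coef(ref)[e]),
                 tolerance = 1e-10)
  }
})

test_that("prediction is the fitted linear predictor, no refitting", {
  set.seed(46)
  n <- 50
  tab <- data.frame(age = stats::rnorm(n, 30), sex = stats::rbinom(n, 1, .5),
                    bmi = stats::rnorm(n, 25), ftnd = stats::rpois(n, 1),
                    e1 = stats::rnorm(n))
  tab$y <- 3 - 0.2 * tab$e1 + 0.05 * tab$bmi + stats::rnorm(n)
  fit <- fitGlm("y", tab, edgeCols = "e1")
  expect_equal(predictApply(fit, tab),
               unname(stats::predict(stats::lm(
                 y ~ e1 + age + sex + bmi + ftnd, tab))),
               tolerance = 1e-10)
  new <- tab[1:5, ]
  new$e1 <- new$e1 + 1
  ref <- stats::lm(y ~ e1 + age + sex + bmi + ftnd, tab)
  expect_equal(predictApply(fit, new),
               unname(stats::predict(ref, newdata = new)), tolerance = 1e-10)
  expect_error(predictApply(fit, new[setdiff(names(new), "e1")]), "e1")
  ## covariate-only model still predicts
  fit0 <- fitGlm("y", tab)
  expect_length(predictApply(fit0, new), 5)
})
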