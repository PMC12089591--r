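test_that("generator emits the configured dimensions and components", {
  run <- studyRun()
  cfg <- run$cfg
  expect_equal(nMaps(run$maps), cfg$nNodes)
  expect_equal(unname(gridDim(run$maps)), cfg$gridShape)
  expect_length(run$ts, cfg$nSubjects)
  expect_equal(dim(series(run$ts[[1]])), c(cfg$nTimepoints, cfg$nNodes))
  expect_equal(dim(run$rp[[1]]), c(cfg$nTimepoints, 6L))
  expect_equal(repetitionTime(run$ts[[1]]), cfg$tr)
  ## exactly one designated violation type per noise IC
  expect_equal(sum(run$truth$noiseFlags), length(unlist(cfg$noiseIcs)))
  expect_setequal(which(run$truth$noiseFlags), unlist(cfg$noiseIcs))
})

test_that("generation is deterministic in the seed and sensitive to it", {
  cfg <- tinyConfig(seed = 7L)
  a <- genSpatialMaps(cfg)
  b <- genSpatialMaps(cfg)
  expect_identical(a$maps@maps, b$maps@maps)
  tsA <- genTimeseries(cfg, a$truth)
  tsB <- genTimeseries(cfg, b$truth)
  expect_identical(series(tsA$ts[[1]]), series(tsB$ts[[1]]))
  em <- matrix(stats::rnorm(4 * 66), 4, 66)
  phA <- genPhenotypes(cfg, em, a$truth)
  phB <- genPhenotypes(cfg, em, a$truth)
  expect_identical(phA, phB)
  cfg2 <- tinyConfig(seed = 8L)
  c2 <- genSpatialMaps(cfg2)
  expect_false(identical(a$maps@maps, c2$maps@maps))
})

test_that("noise ICs violate exactly their designated spatial feature", {
  run <- studyRun()
  cls <- run$classification
  th <- qcThresholds()
  edgeIcs <- run$cfg$noiseIcs$edge
  csfIcs <- run$cfg$noiseIcs$csf
  expect_true(all(cls$edgeFraction[edgeIcs] > th$edgeFraction))
  expect_true(all(cls$csfFraction[csfIcs] > th$csfFraction))
  signal <- !run$truth$noiseFlags
  expect_true(all(cls$edgeFraction[signal] <= th$edgeFraction))
  expect_true(all(cls$csfFraction[signal] <= th$csfFraction))
})

test_that("planted population edge correlation survives into sample r", {
  n <- 8L
  cfg <- syntheticConfig(seed = 3L, nSubjects = 200L, nNodes = n,
                         nTimepoints = 1200L, gridShape = c(12L, 12L, 12L),
                         noiseIcs = list(edge = integer(0), csf = integer(0),
                                         rp = integer(0), hf = integer(0)),
                         plantedEdges = data.frame(
                           edge = pairToEdge(1L, 2L, n), score = "odor",
                           weight = 1, popR = 0.5))
  tsr <- genTimeseries(cfg, allSignalTruth(n))
  rs <- vapply(tsr$ts, function(ts) stats::cor(series(ts)[, 1],
                                               series(ts)[, 2]), numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.05)
  ## unplanted pair stays near zero on average
  r0 <- vapply(tsr$ts, function(ts) stats::cor(series(ts)[, 3],
                                               series(ts)[, 4]), numeric(1))
  expect_lt(abs(mean(r0)), 0.05)
})

test_that("per-subject correlation matrices are valid correlation matrices", {
  cfg <- tinyConfig(seed = 5L, nSubjects = 3L)
  tsr <- genTimeseries(cfg, allSignalTruth(cfg$nNodes))
  for (ts in tsr$ts) {
    M <- connMatrix(buildConnectome(ts))
    expect_true(isSymmetric(M, tol = 1e-12))
    expect_equal(unname(diag(M)), rep(1, cfg$nNodes))
    expect_true(all(M >= -1 & M <= 1))
    expect_gte(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("zero effect weights leave edge-score correlations centred at 0", {
  n <- 12L
  nulled <- data.frame(edge = pairToEdge(1L, 2L, n), score = "odor",
                       weight = 0, popR = 0)
  em <- matrix(stats::rnorm(400 * n * (n - 1) / 2), nrow = 400)
  rs <- vapply(1:100, function(s) {
    cfg <- tinyConfig(seed = s, nSubjects = 400L, missingRate = 0,
                      plantedEdges = nulled)
    tab <- genPhenotypes(cfg, em, allSignalTruth(n, plantedEdges = nulled))
    stats::cor(em[, nulled$edge], tab$odor)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("a noise-free score reproduces its planted edge exactly", {
  n <- 12L
  pe <- data.frame(edge = pairToEdge(3L, 4L, n), score = "odor",
                   weight = 1, popR = 0.3)
  cfg <- tinyConfig(seed = 2L, nSubjects = 50L, missingRate = 0,
                    plantedEdges = pe, scoreNoiseSd = 0)
  em <- matrix(stats::rnorm(50 * n * (n - 1) / 2), nrow = 50)
  tab <- genPhenotypes(cfg, em, allSignalTruth(n, plantedEdges = pe))
  expect_equal(stats::cor(tab$odor, em[, pe$edge]), 1, tolerance = 1e-12)
})

test_that("missingness is MCAR at the configured rate and propagates", {
  cfg <- tinyConfig(seed = 4L, nSubjects = 500L, missingRate = 0.1)
  em <- matrix(stats::rnorm(500 * 66), nrow = 500)
  tab <- genPhenotypes(cfg, em, allSignalTruth(12L))
  mask <- attr(tab, "missingMask")
  expect_lt(abs(mean(mask) - 0.1), 0.01)
  ## recoded categories are missing exactly where their raw value is
  expect_identical(is.na(tab$drinksPerDayCode), is.na(tab$drinksPerDayRaw))
  expect_identical(is.na(tab$maxDrinksCode), is.na(tab$maxDrinksRaw))
  ## covariates age and sex are never blanked
  expect_false(anyNA(tab$age))
  expect_false(anyNA(tab$sex))
})

test_that("genEdgeMatrix plants the requested edge-score correlation", {
  g <- genEdgeMatrix(4000, 20, planted = c(3L, 7L), plantedR = 0.3, seed = 9L)
  expect_equal(dim(g$edges), c(4000L, 20L))
  expect_lt(abs(stats::cor(g$edges[, 3], g$score) - 0.3), 0.05)
  expect_lt(abs(stats::cor(g$edges[, 7], g$score) - 0.3), 0.05)
  expect_lt(abs(stats::cor(g$edges[, 1], g$score)), 0.05)
  expect_identical(g, genEdgeMatrix(4000, 20, planted = c(3L, 7L),
                                    plantedR = 0.3, seed = 9L))
})

test_that("configuration validation rejects inconsistent setups", {
  expect_error(syntheticConfig(nTimepoints = 32), "64")
  expect_error(tinyConfig(plantedEdges = data.frame(
    edge = pairToEdge(9L, 10L, 12L), score = "odor", weight = 1, popR = 0.3)),
    "non-noise")
  expect_error(syntheticConfig(noiseIcs = list(edge = 1L, csf = 1L,
                                               rp = 2L, hf = 3L)),
               "one designated noise type")
})
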