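test_that("mask dilation matches a brute-force voxel-loop oracle", {
  ## single centre voxel, face connectivity: itself plus 6 face neighbours
  a <- array(0, dim = c(5, 5, 5))
  a[3, 3, 3] <- 1
  d6 <- dilateMask(a, connectivity = 6)
  expect_equal(sum(d6), 7)
  expect_equal(d6, bruteDilate(a, 6))
  expect_equal(sum(dilateMask(a, connectivity = 18)), 19)
  expect_equal(sum(dilateMask(a, connectivity = 26)), 27)
  set.seed(42)
  for (conn in c(6, 18, 26)) {
    m <- array(as.numeric(stats::runif(7^3) < 0.2), dim = c(7, 7, 7))
    expect_equal(dilateMask(m, connectivity = conn), bruteDilate(m, conn))
  }
  ## two passes equal one pass of the once-dilated mask
  m <- array(0, dim = c(9, 9, 9)); m[5, 5, 5] <- 1
  expect_equal(dilateMask(m, iterations = 2), dilateMask(dilateMask(m)))
  expect_error(dilateMask(m, connectivity = 7), "connectivity")
})

test_that("the edge mask is a non-empty shell disjoint from the brain", {
  run <- studyRun()
  brain <- brainMask(run$masks)
  edge <- edgeMask(run$masks)
  expect_gt(sum(edge), 0)
  expect_equal(sum(edge * brain), 0)
  ## every edge voxel is face-adjacent to the brain (it came from dilation)
  expect_equal(edge, dilateMask(brain) - brain)
  full <- array(1, dim = c(4, 4, 4))
  expect_warning(makeEdgeMask(full), "empty")
  expect_error(makeEdgeMask(array(0, dim = c(4, 4, 4))), "empty")
})

test_that("intensity fractions follow their closed forms", {
  g <- c(4, 4, 4)
  m <- array(0, dim = g)
  m[1:2, , ] <- 1
  vol <- array(1, dim = g)
  expect_equal(fractionInMask(vol, m), 0.5)
  expect_equal(fractionInMask(vol, array(1, dim = g)), 1)
  ## signed map: 3 voxels of -1 inside, 9 voxels of +1 outside -> 3/12
  v <- array(0, dim = g)
  inm <- array(0, dim = g)
  v[1, 1, 1:3] <- -1
  inm[1, 1, 1:3] <- 1
  v[2, 2, 1:4] <- 1; v[3, 3, 1:4] <- 1; v[4, 4, 1] <- 1
  expect_equal(fractionInMask(v, inm), 0.25)
  ## invariant to positive rescaling of the map
  expect_equal(fractionInMask(7 * v, inm), fractionInMask(v, inm))
  expect_error(fractionInMask(array(0, dim = g), inm), "all-zero")
  expect_error(fractionInMask(vol, array(1, dim = c(3, 3, 3))), "grid")
})

test_that("maximum realignment-parameter correlation behaves as a sup of |r|", {
  set.seed(1)
  rp <- matrix(stats::rnorm(100 * 6), 100, 6)
  expect_equal(maxRpCorrelation(rp[, 4], rp), 1)
  expect_equal(maxRpCorrelation(-rp[, 4], rp), 1)
  ## residualizing a series against all rp columns drives the feature to ~0
  x <- stats::rnorm(100)
  resid <- stats::lm.fit(cbind(1, rp), x)$residuals
  expect_lt(maxRpCorrelation(resid, rp), 1e-10)
  ## scale invariance
  expect_equal(maxRpCorrelation(3 * x + 2, rp), maxRpCorrelation(x, rp))
  expect_error(maxRpCorrelation(rep(1, 100), rp), "constant")
})

test_that("spectral band fractions localize sinusoids correctly", {
  tr <- 0.72
  t <- seq_len(600)
  slow <- sin(2 * pi * 0.02 * t * tr)      # 0.02 Hz, below the 0.1 Hz cutoff
  fast <- sin(2 * pi * 0.50 * t * tr)      # 0.50 Hz, above it
  expect_lt(highFreqContent(slow, tr), 0.05)
  expect_gt(highFreqContent(fast, tr), 0.95)
  ## a mixture splits its power between the bands
  mix <- highFreqContent(slow + fast, tr)
  expect_gt(mix, 0.3)
  expect_lt(mix, 0.7)
  expect_error(highFreqContent(slow, tr, cutoffHz = 0.7), "Nyquist")
  expect_error(highFreqContent(slow[1:32], tr), "64")
  ## Welch grid: frequencies run 0 .. Nyquist
  psd <- welchPsd(slow, tr)
  expect_equal(psd$freq[1], 0)
  expect_equal(max(psd$freq), 1 / (2 * tr) * (256 / 2) / (256 / 2))
  expect_true(all(psd$power >= 0))
})

test_that("IC classification is boundary-inclusive and monotone", {
  th <- qcThresholds()
  atBoundary <- data.frame(
    subject = rep(c("s1", "s2"), each = 2),
    ic = rep(c("a", "b"), 2),
    edgeFraction = th$edgeFraction,
    csfFraction = th$csfFraction,
    maxRpCorr = th$maxRpCorr,
    hfContent = th$hfContent)
  cls <- aggregateAndClassify(atBoundary, th)
  expect_true(all(cls$signal))             # exactly at threshold = signal
  above <- atBoundary
  above$hfContent[above$ic == "b"] <- th$hfContent + 1e-9
  cls2 <- aggregateAndClassify(above, th)
  expect_equal(cls2$signal, c(a = TRUE, b = FALSE), ignore_attr = TRUE)
  ## monotone: relaxing every threshold can only add signal ICs
  set.seed(10)
  feats <- data.frame(subject = rep(c("s1", "s2"), each = 30),
                      ic = rep(sprintf("ic%02d", 1:30), 2),
                      edgeFraction = stats::runif(60),
                      csfFraction = stats::runif(60),
                      maxRpCorr = stats::runif(60),
                      hfContent = stats::runif(60))
  tight <- qcThresholds(0.3, 0.2, 0.3, 0.2)
  loose <- qcThresholds(0.7, 0.6, 0.7, 0.6)
  sTight <- aggregateAndClassify(feats, tight)$signal
  sLoose <- aggregateAndClassify(feats, loose)$signal
  expect_true(all(sLoose[sTight]))
  ## unbalanced tables are rejected
  expect_error(aggregateAndClassify(feats[-1, ], th), "cells")
})

test_that("network assignment recovers labels by spatial correlation", {
  run <- studyRun()
  refs <- makeReferenceMaps(run$maps, run$truth$networkLabel)
  asg <- assignNetworks(run$maps, refs, mask = brainMask(run$masks))
  signal <- !run$truth$noiseFlags
  ## reference maps are means over 4 random member blobs, so best-match
  ## recovery of the generating label is strong but not guaranteed per IC
  expect_true(all(asg$label[signal] %in% run$truth$networkLabel[signal]))
  agree <- mean(asg$label[signal] == run$truth$networkLabel[signal])
  expect_gte(agree, 0.75)
  expect_true(all(asg$correlation[signal] > 0.2))
  ## self-assignment: using the maps themselves as references gives r = 1
  self <- assignNetworks(run$maps, run$maps)
  expect_equal(self$label, icIds(run$maps))
  expect_equal(self$correlation, rep(1, nMaps(run$maps)), tolerance = 1e-8)
})

test_that("volume resampling is exact on matching grids and for constants", {
  set.seed(3)
  v <- array(stats::rnorm(6^3), dim = c(6, 6, 6))
  expect_equal(resampleVolume(v, c(6, 6, 6), "nearest"), v, ignore_attr = TRUE)
  cst <- array(5, dim = c(6, 6, 6))
  up <- resampleVolume(cst, c(9, 9, 9), "linear")
  expect_equal(up, array(5, dim = c(9, 9, 9)))
  expect_equal(dim(resampleVolume(v, c(3, 4, 5), "linear")), c(3L, 4L, 5L))
})
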