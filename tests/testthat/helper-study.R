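## Shared fixtures. `studyRun()` runs the generator + QC chain once under the
## default study conditions and memoizes the result so several test files can
## inspect it without regenerating. `tinyConfig()` is a fast configuration for
## structural tests where the study-scale dimensions are irrelevant.

.studyEnv <- new.env(parent = emptyenv())

studyRun <- function() {
  if (is.null(.studyEnv$run)) {
    cfg <- syntheticConfig(seed = 1L)
    sm <- genSpatialMaps(cfg)
    tsr <- genTimeseries(cfg, sm$truth)
    feats <- computeIcFeatures(sm$maps, sm$masks, tsr$ts, tsr$rp)
    cls <- aggregateAndClassify(feats, qcThresholds())
    .studyEnv$run <- list(cfg = cfg, maps = sm$maps, masks = sm$masks,
                          truth = sm$truth, ts = tsr$ts, rp = tsr$rp,
                          features = feats, classification = cls)
  }
  .studyEnv$run
}

tinyConfig <- function(seed = 1L, nSubjects = 4L, nTimepoints = 128L,
                       missingRate = 0.05, ...) {
  syntheticConfig(seed = seed, nSubjects = nSubjects, nNodes = 12L,
                  nTimepoints = nTimepoints, gridShape = c(12L, 12L, 12L),
                  noiseIcs = list(edge = 9L, csf = 10L, rp = 11L, hf = 12L),
                  missingRate = missingRate, ...)
}

## truth object sufficient for genTimeseries() when no maps are needed
allSignalTruth <- function(nNodes, plantedEdges = data.frame()) {
  structure(list(noiseType = rep("signal", nNodes),
                 noiseFlags = rep(FALSE, nNodes),
                 plantedEdges = plantedEdges,
                 networkLabel = rep(NA_character_, nNodes)),
            class = "GroundTruth")
}
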