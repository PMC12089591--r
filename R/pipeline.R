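#' Full run configuration
#'
#' One object steering the end-to-end pipeline: the synthetic cohort, the
#' quality-control thresholds, the selection rule, the model options and the
#' global seed. Every stage derives its own seed from the global one so that
#' stages re-run independently yet reproducibly.
#'
#' @param synthetic a [syntheticConfig()].
#' @param thresholds a [qcThresholds()].
#' @param selection a [selectionConfig()] template (applied once per score).
#' @param outcomes outcome columns to model (default: the generated count
#'   outcomes and the recoded past-year categories).
#' @param covariates confounder columns entering every GLM.
#' @param trainFraction training fraction of the subject split.
#' @param matchCaliper caliper (training-sd units) for the matched validation
#'   subset.
#' @param imputeK neighbours for proximity imputation.
#' @param seed global seed; stage seeds are derived from it.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(synthetic = syntheticConfig(),
                      thresholds = qcThresholds(),
                      selection = selectionConfig(),
                      outcomes = c("totalDrinks7", "wine7",
                                   "beerWineCooler7", "drinksPerDayCode",
                                   "maxDrinksCode"),
                      covariates = c("age", "sex", "bmi", "ftnd"),
                      trainFraction = 0.7,
                      matchCaliper = 0.25,
                      imputeK = 10L,
                      seed = 1L) {
  cfg <- list(synthetic = synthetic, thresholds = thresholds,
              selection = selection, outcomes = outcomes,
              covariates = covariates, trainFraction = trainFraction,
              matchCaliper = matchCaliper, imputeK = imputeK,
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

stageSeed <- function(seed, stage) {
  offsets <- c(simulate = 0L, split = 10L)
  (seed + offsets[[stage]]) %% .Machine$integer.max
}

runStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes simulate -> qc -> connectome -> select -> fit -> predict ->
#' evaluate on a synthetic cohort, writing every stage's outputs plus a
#' provenance manifest (seed, effective parameters, file hashes) under
#' `outDir`.
#'
#' @param config a [runConfig()].
#' @param outDir run directory (created; partial outputs are preserved on
#'   stage failure).
#' @return invisibly, a list with the in-memory stage results: `truth`,
#'   `classification`, `signalIcs`, `selection` (per score), `fits`,
#'   `reports`, `comparability`, `chemoCorrelations`, `manifest`.
#' @export
runPipeline <- function(config = runConfig(), outDir = tempfile("chemoconn")) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  syn <- config$synthetic
  syn$seed <- as.integer(stageSeed(config$seed, "simulate"))

  ## -- simulate ------------------------------------------------------------
  sim <- runStage("simulate", {
    sm <- genSpatialMaps(syn)
    tsr <- genTimeseries(syn, sm$truth)
    conns <- lapply(tsr$ts, buildConnectome)
    fullEdges <- edgeMatrix(conns)
    tab <- genPhenotypes(syn, fullEdges, sm$truth)
    writeMaskSet(sm$masks, file.path(outDir, "masks"))
    writeSpatialMaps(sm$maps, file.path(outDir, "ic_maps.nii.gz"))
    writeTimeseries(tsr$ts, file.path(outDir, "timeseries"), tsr$rp)
    writeSubjectTable(tab, file.path(outDir, "subjects.tsv"))
    jsonlite::write_json(
      list(noiseType = sm$truth$noiseType,
           plantedEdges = sm$truth$plantedEdges,
           networkLabel = sm$truth$networkLabel),
      file.path(outDir, "ground_truth.json"), auto_unbox = FALSE)
    list(maps = sm$maps, masks = sm$masks, truth = sm$truth,
         ts = tsr$ts, rp = tsr$rp, conns = conns, table = tab)
  })

  ## -- qc -------------------------------------------------------------------
  qc <- runStage("qc", {
    feats <- computeIcFeatures(sim$maps, sim$masks, sim$ts, sim$rp)
    cls <- aggregateAndClassify(feats, config$thresholds)
    utils::write.table(feats, file.path(outDir, "qc_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cls, file.path(outDir, "qc_classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(features = feats, classification = cls,
         signalIcs = cls$ic[cls$signal])
  })

  ## -- connectome ----------------------------------------------------------
  conn <- runStage("connectome", {
    em <- edgeMatrix(sim$conns, keepNodes = qc$signalIcs)
    writeEdgeMatrixFile(em, file.path(outDir, "edges_signal.tsv"))
    em
  })

  ## -- impute + split (data preparation) ------------------------------------
  prep <- runStage("prepare", {
    tab <- imputeProximity(sim$table, k = config$imputeK)
    tab$drinksPerDayCode <- recodeDrinksPerDay(pmax(0, round(tab$drinksPerDayRaw)))
    tab$maxDrinksCode <- recodeMaxDrinks(pmax(1, round(tab$maxDrinksRaw)),
                                         tab$sex)
    part <- splitTrainValidation(tab, config$trainFraction,
                                 seed = stageSeed(config$seed, "split"))
    tab$partition <- as.character(part)
    writeSubjectTable(tab, file.path(outDir, "subjects_prepared.tsv"))
    tab
  })
  train <- prep[prep$partition == "train", , drop = FALSE]
  valid <- prep[prep$partition == "validation", , drop = FALSE]
  trainEdges <- conn[prep$partition == "train", , drop = FALSE]
  validEdges <- conn[prep$partition == "validation", , drop = FALSE]

  ## -- select ---------------------------------------------------------------
  selection <- runStage("select", {
    out <- list()
    for (sc in c("odor", "taste")) {
      cfgS <- config$selection
      cfgS$score <- sc
      full <- edgewiseCorrelation(trainEdges, train[[sc]])
      loo <- loocvPvalues(trainEdges, train[[sc]])
      res <- selectEdges(loo, full, cfgS)
      utils::write.table(res,
                         file.path(outDir, paste0("selection_", sc, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[sc]] <- res
    }
    out
  })

  ## -- fit + predict + evaluate ---------------------------------------------
  addEdgeCols <- function(tab, edges, sel) {
    picked <- sel$edge[sel$selected]
    cols <- paste0("edge", picked, recycle0 = TRUE)
    for (k in seq_along(picked))
      tab[[cols[k]]] <- edges[, picked[k]]
    list(tab = tab, cols = cols)
  }
  match <- runStage("match", {
    matchValidation(valid, train, keys = c("odor", "taste"),
                    caliper = config$matchCaliper)
  })
  fits <- list(); reports <- list()
  runStage("fit_predict_evaluate", {
    for (sc in c("odor", "taste")) {
      tr <- addEdgeCols(train, trainEdges, selection[[sc]])
      va <- addEdgeCols(valid, validEdges, selection[[sc]])
      for (oc in config$outcomes) {
        fit <- fitGlm(oc, tr$tab, edgeCols = tr$cols,
                      covariates = config$covariates)
        pred <- predictApply(fit, va$tab)
        med <- stats::median(prep[[oc]], na.rm = TRUE)
        rep1 <- cbind(score = sc, outcome = oc,
                      as.data.frame(t(regressionMetrics(pred, va$tab[[oc]]))),
                      medianSplitMetrics(pred, va$tab[[oc]], med))
        fits[[paste(sc, oc, sep = ".")]] <- fit
        reports[[paste(sc, oc, sep = ".")]] <- rep1
      }
    }
  })
  reportTab <- do.call(rbind, reports)
  rownames(reportTab) <- NULL
  utils::write.table(reportTab, file.path(outDir, "prediction_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comp <- runStage("evaluate", groupCompare(train, match$matched))
  chem <- runStage("evaluate", chemosensoryAlcoholCorrelations(prep))
  utils::write.table(comp, file.path(outDir, "comparability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(chem, file.path(outDir, "chemo_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- manifest --------------------------------------------------------------
  files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    seed = config$seed,
    stageSeeds = list(simulate = syn$seed,
                      split = stageSeed(config$seed, "split")),
    packageVersion = as.character(utils::packageVersion("chemoconn")),
    parameters = list(
      nSubjects = syn$nSubjects, nNodes = syn$nNodes,
      nTimepoints = syn$nTimepoints, tr = syn$tr,
      thresholds = unclass(config$thresholds),
      selection = unclass(config$selection),
      trainFraction = config$trainFraction,
      matchCaliper = config$matchCaliper, imputeK = config$imputeK),
    nSelected = lapply(selection, function(s) sum(s$selected)),
    fileHashes = as.list(tools::md5sum(file.path(outDir, files)))
  )
  names(manifest$fileHashes) <- files
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(truth = sim$truth, classification = qc$classification,
                 signalIcs = qc$signalIcs, table = prep,
                 selection = selection, fits = fits, reports = reportTab,
                 comparability = comp, chemoCorrelations = chem,
                 matched = match$matched,
                 manifest = file.path(outDir, "manifest.json"),
                 outDir = outDir))
}
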