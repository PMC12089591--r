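## Boundary formats: NIfTI volumes for maps/masks, tab-delimited tables with
## a header comment naming the edge-index convention, JSON sidecars.

edgeConventionComment <- paste(
  "# edges: upper triangle (i < j), row-major order (1,2),(1,3),...,",
  "1-based indices")

#' Write / read a mask set as NIfTI volumes
#'
#' @param masks a [MaskSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeMaskSet <- function(masks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("brain.nii.gz", "edge.nii.gz", "csf.nii.gz"))
  RNifti::writeNifti(brainMask(masks), paths[1])
  RNifti::writeNifti(edgeMask(masks), paths[2])
  RNifti::writeNifti(csfMask(masks), paths[3])
  invisible(paths)
}

#' @rdname writeMaskSet
#' @export
readMaskSet <- function(dir) {
  rd <- function(f) {
    v <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(round(v)), dim = dim(v))
  }
  new("MaskSet", brain = rd("brain.nii.gz"), edge = rd("edge.nii.gz"),
      csf = rd("csf.nii.gz"), voxelSize = c(2, 2, 2))
}

#' Write / read IC spatial maps as one 4-d NIfTI volume
#'
#' @param mapSet a [SpatialMapSet-class].
#' @param file output path (.nii.gz); IC identifiers go to a JSON sidecar.
#' @export
writeSpatialMaps <- function(mapSet, file) {
  RNifti::writeNifti(mapSet@maps, file)
  jsonlite::write_json(list(icIds = icIds(mapSet)),
                       paste0(file, ".json"), auto_unbox = FALSE)
  invisible(file)
}

#' @rdname writeSpatialMaps
#' @export
readSpatialMaps <- function(file) {
  v <- RNifti::readNifti(file)
  ids <- jsonlite::read_json(paste0(file, ".json"),
                             simplifyVector = TRUE)$icIds
  new("SpatialMapSet", maps = array(as.numeric(v), dim = dim(v)),
      icIds = as.character(ids))
}

#' Write / read the subject table (tab-delimited)
#'
#' @param table subject data.frame.
#' @param file output path.
#' @export
writeSubjectTable <- function(table, file) {
  utils::write.table(table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writeSubjectTable
#' @export
readSubjectTable <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' Write / read a subjects x edges matrix with its JSON edge-index sidecar
#'
#' @param m numeric matrix from [edgeMatrix()].
#' @param file output path (tab-delimited; a header comment records the edge
#'   ordering convention).
#' @export
writeEdgeMatrixFile <- function(m, file) {
  con <- file(file, "w")
  writeLines(edgeConventionComment, con)
  utils::write.table(as.data.frame(m), con, sep = "\t", quote = FALSE,
                     row.names = !is.null(rownames(m)))
  close(con)
  ids <- attr(m, "nodeIds")
  jsonlite::write_json(
    list(nodeIds = if (is.null(ids)) character(0) else ids,
         ordering = "row-major upper triangle, i < j, 1-based"),
    paste0(file, ".json"), auto_unbox = FALSE)
  invisible(file)
}

#' @rdname writeEdgeMatrixFile
#' @export
readEdgeMatrixFile <- function(file) {
  df <- utils::read.delim(file, comment.char = "#", check.names = FALSE)
  hasRownames <- !is.numeric(df[[1]])
  if (hasRownames) {
    rn <- df[[1]]
    df <- df[-1]
    m <- as.matrix(df)
    rownames(m) <- rn
  } else m <- as.matrix(df)
  side <- paste0(file, ".json")
  if (file.exists(side)) {
    ids <- jsonlite::read_json(side, simplifyVector = TRUE)$nodeIds
    if (length(ids)) attr(m, "nodeIds") <- as.character(ids)
  }
  m
}

#' Write per-subject node time series as tab-delimited matrices
#'
#' One file per subject (`<subject>_ts.tsv`), plus `<subject>_rp.tsv` for the
#' realignment parameters when given.
#'
#' @param tsList list of [NodeTimeSeries-class].
#' @param rpList optional parallel list of T x 6 matrices.
#' @param dir output directory.
#' @export
writeTimeseries <- function(tsList, dir, rpList = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(tsList)) {
    id <- subjectId(tsList[[s]])
    utils::write.table(series(tsList[[s]]),
                       file.path(dir, paste0(id, "_ts.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rpList))
      utils::write.table(rpList[[s]],
                         file.path(dir, paste0(id, "_rp.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = paste0("rp", 1:6))
  }
  invisible(dir)
}
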