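#' Canonical edge indexing
#'
#' Connectome edges are the upper-triangle entries (i < j) enumerated
#' row-major: (1,2), (1,3), ..., (1,N), (2,3), ... Edge indices are 1-based.
#' `edgeIndexMap` tabulates the bijection, `pairToEdge` and `edgeToPair`
#' convert in either direction.
#'
#' @param nNodes number of nodes N.
#' @return `edgeIndexMap`: data.frame with columns `edge`, `i`, `j`
#'   (E = N(N-1)/2 rows).
#' @export
edgeIndexMap <- function(nNodes) {
  stopifnot(nNodes >= 2)
  i <- rep(seq_len(nNodes - 1L), times = (nNodes - 1L):1L)
  j <- unlist(lapply(seq_len(nNodes - 1L), function(a) (a + 1L):nNodes))
  data.frame(edge = seq_along(i), i = i, j = j)
}

#' @rdname edgeIndexMap
#' @param i,j node indices with i < j.
#' @export
pairToEdge <- function(i, j, nNodes) {
  stopifnot(all(i >= 1), all(j > i), all(j <= nNodes))
  as.integer((i - 1) * (2 * nNodes - i) / 2 + (j - i))
}

#' @rdname edgeIndexMap
#' @param edge edge index vector.
#' @export
edgeToPair <- function(edge, nNodes) {
  map <- edgeIndexMap(nNodes)
  stopifnot(all(edge >= 1), all(edge <= nrow(map)))
  map[edge, c("i", "j"), drop = FALSE]
}

#' Extract node time series by spatial regression (dual-regression stage 1)
#'
#' Regresses, at every timepoint, the 4-d data volume on all IC spatial maps
#' jointly; the T x N matrix of regression coefficients is the per-node time
#' series.
#'
#' @param fmri4d 4-d array (x, y, z, t) on the same grid as `maps`.
#' @param maps a [SpatialMapSet-class].
#' @param subject subject identifier carried into the result.
#' @param tr repetition time in seconds.
#' @return a [NodeTimeSeries-class].
#' @export
extractNodeTimeseries <- function(fmri4d, maps, subject = "s1", tr = 0.72) {
  stopifnot(length(dim(fmri4d)) == 4)
  if (!identical(dim(fmri4d)[1:3], unname(gridDim(maps))))
    stop("4-d data and maps must share a grid")
  nT <- dim(fmri4d)[4]
  X <- matrix(maps@maps, ncol = nMaps(maps))          # voxels x N
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    stop("rank-deficient map matrix; collinear maps: ",
         paste(icIds(maps)[drop], collapse = ", "))
  }
  Y <- matrix(fmri4d, ncol = nT)                      # voxels x T
  beta <- qr.coef(qrX, Y)                             # N x T
  new("NodeTimeSeries", subject = subject,
      series = structure(t(beta), dimnames = list(NULL, icIds(maps))),
      tr = tr)
}

#' Build a functional connectome
#'
#' Pairwise Pearson correlation matrix of the node time series, diagonal set
#' to exactly 1.
#'
#' @param ts a [NodeTimeSeries-class] with at least 3 timepoints.
#' @return a [Connectome-class].
#' @export
buildConnectome <- function(ts) {
  X <- series(ts)
  if (nrow(X) < 3) stop("need at least 3 timepoints")
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    bad <- colnames(X)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("zero-variance node(s): ", paste(bad, collapse = ", "))
  }
  M <- stats::cor(X)
  diag(M) <- 1
  M[M > 1] <- 1; M[M < -1] <- -1
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("node", seq_len(ncol(X)))
  new("Connectome", subject = subjectId(ts), matrix = unname(M),
      nodeIds = ids)
}

#' Vectorize a connectome's upper triangle
#'
#' Restricts the matrix to `keepNodes` (typically the signal ICs) and emits
#' the upper-triangle entries in the canonical row-major order of
#' [edgeIndexMap()]. `devectorizeEdges` inverts the operation to a symmetric
#' unit-diagonal matrix.
#'
#' @param conn a [Connectome-class].
#' @param keepNodes node identifiers or indices to retain (default: all).
#' @return named numeric vector of length E = k(k-1)/2, names "id1|id2";
#'   attribute `nodeIds` records the retained node order.
#' @export
vectorizeEdges <- function(conn, keepNodes = NULL) {
  M <- connMatrix(conn)
  ids <- nodeIds(conn)
  if (is.null(keepNodes)) keepNodes <- seq_along(ids)
  if (is.character(keepNodes)) keepNodes <- match(keepNodes, ids)
  if (anyNA(keepNodes)) stop("unknown node in keepNodes")
  if (length(keepNodes) < 2) stop("need at least 2 nodes to form edges")
  M <- M[keepNodes, keepNodes, drop = FALSE]
  ids <- ids[keepNodes]
  # t(M)[lower.tri] enumerates the upper triangle of M row-major
  v <- t(M)[lower.tri(M)]
  map <- edgeIndexMap(length(ids))
  names(v) <- paste(ids[map$i], ids[map$j], sep = "|")
  attr(v, "nodeIds") <- ids
  v
}

#' @rdname vectorizeEdges
#' @param edges edge vector as produced by `vectorizeEdges`.
#' @export
devectorizeEdges <- function(edges) {
  E <- length(edges)
  n <- (1 + sqrt(1 + 8 * E)) / 2
  if (n != round(n)) stop("edge vector length is not N(N-1)/2 for integer N")
  n <- as.integer(round(n))
  M <- diag(1, n)
  M[lower.tri(M)] <- edges      # fills t(upper) row-major
  M <- t(M)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  ids <- attr(edges, "nodeIds")
  if (!is.null(ids)) dimnames(M) <- list(ids, ids)
  M
}

#' Stack per-subject edge vectors into a subjects x edges matrix
#'
#' @param connectomes list of [Connectome-class] objects sharing node ids.
#' @param keepNodes as in [vectorizeEdges()].
#' @return numeric matrix, one row per subject, with subject ids as rownames
#'   and edge names as colnames.
#' @export
edgeMatrix <- function(connectomes, keepNodes = NULL) {
  rows <- lapply(connectomes, vectorizeEdges, keepNodes = keepNodes)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(connectomes, subjectId, character(1))
  m
}
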