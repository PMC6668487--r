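#' Read a connectivity matrix from delimited text
#'
#' Reads one subject's fiber-count connectivity matrix: plain delimited text
#' (comma or tab, auto-detected), no header, row *i* = region *i*, with as
#' many rows and columns as the region table (90 for the default
#' parcellation). The matrix must be exactly symmetric with a zero diagonal
#' and nonnegative whole-number entries; asymmetric input is an error rather
#' than being silently averaged, since tractography fiber counts should
#' already be symmetric and silent repair hides upstream bugs.
#'
#' @param path path to the matrix file.
#' @param regions region table ([regionTable()] by default).
#' @param subjectID subject identifier (defaults to the file stem).
#' @param lesionSide `"left"`, `"right"` or `"unknown"`.
#' @return A raw-state [Connectome-class].
#' @export
readConnectome <- function(path, regions = regionTable(),
                           subjectID = sub("\\.[^.]*$", "", basename(path)),
                           lesionSide = "unknown") {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  w <- as.matrix(read.table(path, sep = sep, header = FALSE,
                            colClasses = "numeric"))
  dimnames(w) <- NULL
  n <- nrow(regions)
  if (nrow(w) != n || ncol(w) != n)
    stop(sprintf("expected a %dx%d matrix, got %dx%d in %s",
                 n, n, nrow(w), ncol(w), path))
  if (any(w < 0)) {
    bad <- which(w < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative entry at row %d, col %d in %s",
                 bad[1], bad[2], path))
  }
  if (any(diag(w) != 0)) {
    bad <- which(diag(w) != 0)[1]
    stop(sprintf("non-zero diagonal at (%d,%d) in %s", bad, bad, path))
  }
  if (any(w != t(w))) {
    bad <- which(w != t(w), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE][1, ]
    stop(sprintf("asymmetric matrix: entry (%d,%d)=%g but (%d,%d)=%g in %s",
                 bad[1], bad[2], w[bad[1], bad[2]],
                 bad[2], bad[1], w[bad[2], bad[1]], path))
  }
  connectome(w, regions = regions, subjectID = subjectID,
             lesionSide = lesionSide, state = "raw")
}

#' Threshold raw fiber counts
#'
#' Removes likely-spurious connections by zeroing every entry below a
#' minimum fiber count. The boundary is kept: an edge with exactly `wMin`
#' fibers survives (a *minimum* threshold). The default of 10 fibers is the
#' conventional choice; robustness is usually checked by sweeping the
#' threshold over 5..15 (see [thresholdSweep()]).
#'
#' @param x a raw-state [Connectome-class].
#' @param wMin positive minimum fiber count (default 10).
#' @return A thresholded-state `Connectome`. An all-zero result is legal and
#'   raises a warning.
#' @export
setGeneric("applyThreshold", function(x, wMin = 10) {
  standardGeneric("applyThreshold")
})

#' @rdname applyThreshold
#' @export
setMethod("applyThreshold", "Connectome", function(x, wMin = 10) {
  stopifnot(wMin > 0)
  if (x@state != "raw")
    stop("applyThreshold expects a raw-state Connectome")
  w <- x@weights
  w[w < wMin] <- 0
  ne <- sum(w[upper.tri(w)] > 0)
  message(sprintf("applyThreshold: wMin=%g, %d edges survive", wMin, ne))
  if (ne == 0) warning("thresholding removed every edge")
  initialize(x, weights = w, state = "thresholded")
})

#' Normalize a thresholded matrix to its largest entry
#'
#' Divides every weight by the maximum entry so that the strongest
#' connection has weight exactly 1, minimizing overall between-subject
#' differences in connectivity strength. Ratios between edges are preserved.
#'
#' @param x a thresholded-state [Connectome-class].
#' @return A normalized-state `Connectome` with maximum weight 1.
#' @export
setGeneric("normalizeMax", function(x) standardGeneric("normalizeMax"))

#' @rdname normalizeMax
#' @export
setMethod("normalizeMax", "Connectome", function(x) {
  if (x@state != "thresholded")
    stop("normalizeMax expects a thresholded-state Connectome")
  w <- x@weights
  mx <- max(w)
  if (mx == 0) stop("no edges to normalize")
  w <- w / mx
  ## guard against floating error on the maximum itself
  w[w > 1] <- 1
  initialize(x, weights = w, state = "normalized")
})

#' Connected-component sizes
#'
#' Sizes of the connected components of the network, treating any nonzero
#' weight as an edge, in descending order. After thresholding, the largest
#' component is expected to span all regions; disconnected networks are
#' legal (the efficiency metrics handle them) but worth flagging.
#'
#' @param x a [Connectome-class] in any state, or a symmetric matrix.
#' @return Integer vector of component sizes, descending.
#' @export
connectedComponents <- function(x) {
  w <- .asW(x)
  g <- .wgraph(w)
  sort(as.integer(igraph::components(g)$csize), decreasing = TRUE)
}

#' Hemisphere flip and ipsilesional orientation
#'
#' Lateralized group analyses require "ipsilesional" to mean the same stored
#' hemisphere for every subject. `flipHemispheres()` swaps each homotopic
#' left/right region pair (both rows and columns) using the region table's
#' pairing map; it is an involution. `orientIpsilesional()` applies the flip
#' for subjects with right-sided lesions, so that the lesioned hemisphere is
#' always stored on the left-hemisphere indices, and canonicalizes
#' `lesionSide` to `"left"`; left-sided subjects pass through unchanged.
#'
#' Because the flip is a simultaneous row/column permutation, every network
#' metric value is carried to the homotopic partner region and the multiset
#' of metric values is unchanged.
#'
#' @param x a [Connectome-class] (any state).
#' @return A `Connectome` with permuted weights.
#' @export
flipHemispheres <- function(x) {
  stopifnot(is(x, "Connectome"))
  reg <- x@regions
  perm <- match(reg$homotopic_id, reg$id)
  if (anyNA(perm)) stop("region table has no usable homotopic pairing")
  initialize(x, weights = x@weights[perm, perm, drop = FALSE])
}

#' @rdname flipHemispheres
#' @export
orientIpsilesional <- function(x) {
  stopifnot(is(x, "Connectome"))
  side <- x@lesionSide
  if (side == "unknown")
    stop("lesion side unknown: skip lateralized analyses for this subject")
  if (side == "left") return(x)
  y <- flipHemispheres(x)
  initialize(y, lesionSide = "left")
}

#' Standard preprocessing: threshold, check, orient, normalize
#'
#' Convenience wrapper running the canonical preprocessing chain on a raw
#' connectome: fiber-count threshold, connectedness report, optional
#' ipsilesional orientation, max-normalization.
#'
#' @param x raw-state [Connectome-class].
#' @param wMin minimum fiber count (default 10).
#' @param orient flip right-lesion subjects to the canonical orientation
#'   (default TRUE; subjects with unknown lesion side are left unflipped).
#' @return normalized-state `Connectome`.
#' @export
preprocessConnectome <- function(x, wMin = 10, orient = TRUE) {
  y <- suppressMessages(applyThreshold(x, wMin = wMin))
  cs <- connectedComponents(y)
  if (cs[1] < nrow(y@weights))
    warning(sprintf("subject %s: largest component spans %d of %d regions after threshold",
                    y@subjectID, cs[1], nrow(y@weights)))
  if (orient && y@lesionSide != "unknown") y <- orientIpsilesional(y)
  normalizeMax(y)
}

## internal: igraph from a weighted symmetric matrix
.wgraph <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}
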