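#' @import methods
#' @importFrom stats cor lm.fit pnorm pt qnorm quantile rbinom rlnorm rnorm
#'   runif sd t.test fisher.test complete.cases
#' @importFrom utils read.csv write.csv read.table write.table
NULL

.CONN_STATES <- c("raw", "thresholded", "normalized")
.LESION_SIDES <- c("left", "right", "unknown")

#' Connectome: one subject's weighted structural brain network
#'
#' An S4 container for a single subject's undirected weighted brain network:
#' a symmetric nonnegative adjacency matrix (raw entries are integer
#' streamline/fiber counts between parcellated gray-matter regions), the
#' region table describing the parcellation, the subject identifier, the
#' lesion side, and a processing-state tag.
#'
#' The `state` slot tracks the preprocessing stage and gates downstream
#' operations:
#' * `"raw"` — integer fiber counts as produced by tractography;
#' * `"thresholded"` — after [applyThreshold()] removed sub-threshold counts;
#' * `"normalized"` — after [normalizeMax()] divided by the largest entry
#'   (maximum weight exactly 1 unless the network has no edges).
#'
#' Validity enforces: square matrix matching the region table, symmetry,
#' zero diagonal, nonnegativity, whole-number entries when `state = "raw"`,
#' and a unit maximum when `state = "normalized"`.
#'
#' @slot weights numeric matrix, the adjacency matrix.
#' @slot regions data.frame, see [regionTable()].
#' @slot subjectID character scalar.
#' @slot lesionSide one of `"left"`, `"right"`, `"unknown"`.
#' @slot state one of `"raw"`, `"thresholded"`, `"normalized"`.
#'
#' @seealso [connectome()], [readConnectome()], [applyThreshold()],
#'   [normalizeMax()], [computeMetrics()]
#' @export
setClass("Connectome",
  representation(
    weights = "matrix",
    regions = "data.frame",
    subjectID = "character",
    lesionSide = "character",
    state = "character"
  )
)

setValidity("Connectome", function(object) {
  w <- object@weights
  msgs <- character()
  if (!is.numeric(w)) msgs <- c(msgs, "weights must be numeric")
  if (nrow(w) != ncol(w)) msgs <- c(msgs, "weights must be square")
  if (nrow(object@regions) != nrow(w))
    msgs <- c(msgs, sprintf("region table has %d rows but matrix is %dx%d",
                            nrow(object@regions), nrow(w), ncol(w)))
  if (length(msgs)) return(msgs)
  if (anyNA(w)) msgs <- c(msgs, "weights contain NA")
  else {
    if (any(w < 0)) {
      bad <- which(w < 0, arr.ind = TRUE)[1, ]
      msgs <- c(msgs, sprintf("negative weight at (%d,%d)", bad[1], bad[2]))
    }
    if (any(diag(w) != 0)) {
      bad <- which(diag(w) != 0)[1]
      msgs <- c(msgs, sprintf("non-zero diagonal at (%d,%d)", bad, bad))
    }
    if (!isTRUE(all.equal(w, t(w), tolerance = 0, check.attributes = FALSE))) {
      d <- which(w != t(w), arr.ind = TRUE)[1, ]
      msgs <- c(msgs, sprintf("asymmetric weights at (%d,%d)", d[1], d[2]))
    }
    if (identical(object@state, "raw") && any(w != floor(w)))
      msgs <- c(msgs, "raw fiber counts must be whole numbers")
    if (identical(object@state, "normalized") && any(w > 0) &&
        abs(max(w) - 1) > 1e-12)
      msgs <- c(msgs, "normalized matrix must have maximum entry 1")
  }
  if (length(object@state) != 1L || !object@state %in% .CONN_STATES)
    msgs <- c(msgs, "state must be one of raw/thresholded/normalized")
  if (length(object@lesionSide) != 1L ||
      !object@lesionSide %in% .LESION_SIDES)
    msgs <- c(msgs, "lesionSide must be left/right/unknown")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Connectome
#'
#' @param weights symmetric nonnegative square numeric matrix with zero
#'   diagonal (integer-valued when `state = "raw"`).
#' @param regions region table as returned by [regionTable()] or
#'   [makeRegionTable()]; defaults to a generic table sized to the matrix.
#' @param subjectID subject identifier.
#' @param lesionSide `"left"`, `"right"` or `"unknown"`.
#' @param state processing state; see [Connectome-class].
#' @return A [Connectome-class] object.
#' @examples
#' w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- 12
#' connectome(w, subjectID = "toy")
#' @export
connectome <- function(weights, regions = makeRegionTable(nrow(weights)),
                       subjectID = "subject", lesionSide = "unknown",
                       state = "raw") {
  new("Connectome", weights = unname(as.matrix(weights)), regions = regions,
      subjectID = subjectID, lesionSide = lesionSide, state = state)
}

setMethod("show", "Connectome", function(object) {
  w <- object@weights
  ne <- sum(w[upper.tri(w)] > 0)
  cat(sprintf("Connectome '%s': %d regions, %d edges, state=%s, lesion side=%s\n",
              object@subjectID, nrow(w), ne, object@state, object@lesionSide))
  if (ne > 0)
    cat(sprintf("  weight range: [%g, %g] over edges\n",
                min(w[w > 0]), max(w)))
})

#' @describeIn connectome Extract the weighted adjacency matrix.
#' @param x a `Connectome`.
#' @export
setGeneric("connWeights", function(x) standardGeneric("connWeights"))
#' @rdname connectome
#' @export
setMethod("connWeights", "Connectome", function(x) x@weights)

#' @describeIn connectome Extract the region table.
#' @export
setGeneric("connRegions", function(x) standardGeneric("connRegions"))
#' @rdname connectome
#' @export
setMethod("connRegions", "Connectome", function(x) x@regions)

#' @describeIn connectome Extract the subject identifier.
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))
#' @rdname connectome
#' @export
setMethod("subjectID", "Connectome", function(x) x@subjectID)

#' @describeIn connectome Extract the lesion side.
#' @export
setGeneric("lesionSide", function(x) standardGeneric("lesionSide"))
#' @rdname connectome
#' @export
setMethod("lesionSide", "Connectome", function(x) x@lesionSide)

#' @describeIn connectome Extract the processing state.
#' @export
setGeneric("connState", function(x) standardGeneric("connState"))
#' @rdname connectome
#' @export
setMethod("connState", "Connectome", function(x) x@state)

## internal: accept a Connectome (in a required state) or a bare matrix.
## Toy matrices in examples and tests use the bare-matrix path.
.asW <- function(x, requireState = NULL) {
  if (is(x, "Connectome")) {
    if (!is.null(requireState) && !x@state %in% requireState)
      stop(sprintf("Connectome state is '%s' but '%s' is required",
                   x@state, paste(requireState, collapse = "' or '")))
    return(x@weights)
  }
  w <- unname(as.matrix(x))
  stopifnot(is.numeric(w), nrow(w) == ncol(w))
  w
}
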