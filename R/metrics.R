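#' Weighted network measures
#'
#' The measures used for weighted undirected brain networks, following the
#' standard weighted conventions of the Brain Connectivity Toolbox family:
#'
#' * `nodeDegree()` — number of suprathreshold edges incident to each node
#'   (binary degree of the weighted network).
#' * `nodeStrength()` — sum of incident edge weights per node.
#' * `weightedClustering()` — Onnela weighted clustering coefficient:
#'   \deqn{C_i = \frac{1}{k_i (k_i - 1)} \sum_{j,h} (w_{ij} w_{ih} w_{jh})^{1/3}}
#'   with \eqn{C_i = 0} when the degree \eqn{k_i < 2}. Weights are expected
#'   in \[0, 1\] (use [normalizeMax()]).
#' * `shortestPathLengths()` — all-pairs shortest-path distances with edge
#'   length \eqn{1/w_{ij}} (stronger connections are shorter), Dijkstra via
#'   igraph; unreachable pairs are `Inf`, the diagonal is 0.
#' * `characteristicPathLength()` — mean distance over ordered pairs
#'   \eqn{i \neq j}, averaging finite entries only; the number of excluded
#'   infinite pairs is attached as attribute `"excluded"` and reported.
#' * `globalEfficiency()` — \eqn{E_{glob} = \frac{1}{n(n-1)} \sum_{i \neq j}
#'   1/d_{ij}} with \eqn{1/\infty = 0}, so disconnection is handled natively.
#' * `nodalEfficiency()` — \eqn{E_{nodal}(i) = \frac{1}{n-1} \sum_{j \neq i}
#'   1/d_{ij}}; its mean over nodes equals the global efficiency.
#' * `localEfficiency()` — per node, the global efficiency of the subnetwork
#'   induced by the node's neighbors (weights retained, distances
#'   \eqn{1/w}); 0 when the degree is below 2. An index of fault tolerance
#'   and segregation.
#' * `betweennessCentrality()` — shortest-path betweenness with edge lengths
#'   \eqn{1/w}, equal-length path multiplicities split fractionally
#'   (Brandes, via igraph), unnormalized counts over unordered pairs; set
#'   `binary = TRUE` to ignore weights.
#'
#' All functions accept either a normalized-state [Connectome-class] or a
#' bare symmetric matrix (useful for toy networks).
#'
#' @param x normalized-state [Connectome-class] or symmetric numeric matrix.
#' @param dist distance matrix from `shortestPathLengths()`.
#' @param binary for `betweennessCentrality()`, use unit edge lengths.
#' @name networkMetrics
NULL

#' @rdname networkMetrics
#' @export
nodeDegree <- function(x) {
  w <- .asW(x, requireState = c("normalized", "thresholded", "raw"))
  as.integer(rowSums(w > 0))
}

#' @rdname networkMetrics
#' @export
nodeStrength <- function(x) {
  w <- .asW(x, requireState = c("normalized", "thresholded", "raw"))
  rowSums(w)
}

#' @rdname networkMetrics
#' @export
weightedClustering <- function(x) {
  w <- .asW(x, requireState = "normalized")
  if (any(w > 1 + 1e-9))
    warning("weights exceed 1; Onnela clustering expects max-normalized weights")
  k <- rowSums(w > 0)
  w3 <- w^(1 / 3)
  cyc <- diag(w3 %*% w3 %*% w3)   # sum over ordered (j,h) of (w_ij w_jh w_hi)^(1/3)
  ci <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
  as.numeric(ci)
}

#' @rdname networkMetrics
#' @export
shortestPathLengths <- function(x) {
  w <- .asW(x, requireState = "normalized")
  g <- .wgraph(w)
  ew <- igraph::E(g)$weight
  d <- igraph::distances(g, weights = if (length(ew)) 1 / ew else numeric(0),
                         algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

#' @rdname networkMetrics
#' @export
characteristicPathLength <- function(dist) {
  n <- nrow(dist)
  off <- dist[row(dist) != col(dist)]
  fin <- is.finite(off)
  if (!any(fin)) stop("no finite off-diagonal distances: network has no paths")
  excluded <- sum(!fin)
  if (excluded > 0)
    message(sprintf("characteristicPathLength: %d infinite ordered pairs excluded",
                    excluded))
  L <- mean(off[fin])
  attr(L, "excluded") <- excluded
  L
}

#' @rdname networkMetrics
#' @export
globalEfficiency <- function(dist) {
  n <- nrow(dist)
  if (n < 2) return(0)
  inv <- 1 / dist
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' @rdname networkMetrics
#' @export
nodalEfficiency <- function(dist) {
  n <- nrow(dist)
  inv <- 1 / dist
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

#' @rdname networkMetrics
#' @export
localEfficiency <- function(x) {
  w <- .asW(x, requireState = "normalized")
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- w[nb, nb, drop = FALSE]
    g <- .wgraph(sub)
    ew <- igraph::E(g)$weight
    d <- igraph::distances(g, weights = if (length(ew)) 1 / ew else numeric(0),
                           algorithm = "dijkstra")
    globalEfficiency(d)
  }, numeric(1))
}

#' @rdname networkMetrics
#' @export
betweennessCentrality <- function(x, binary = FALSE) {
  w <- .asW(x, requireState = "normalized")
  g <- .wgraph(w)
  ew <- igraph::E(g)$weight
  wts <- if (binary || !length(ew)) rep(1, length(ew)) else 1 / ew
  as.numeric(igraph::betweenness(g, directed = FALSE, weights = wts))
}

#' Compute all global and nodal measures for one subject
#'
#' Single pass producing the global record (mean clustering C, characteristic
#' path length L, global efficiency, mean local efficiency) and the nodal
#' table (degree, strength, clustering, betweenness, nodal and local
#' efficiency per region). Deterministic for fixed input.
#'
#' @param x normalized-state [Connectome-class].
#' @return A list with elements `global` (one-row data.frame: `subject_id`,
#'   `clustering_C`, `path_length_L`, `eff_global`, `eff_local`,
#'   `n_inf_pairs`) and `nodal` (one row per region: `subject_id`,
#'   `region_id`, `region`, `degree`, `strength`, `clustering`,
#'   `betweenness`, `eff_nodal`, `eff_local`).
#' @export
setGeneric("computeMetrics", function(x) standardGeneric("computeMetrics"))

#' @rdname computeMetrics
#' @export
setMethod("computeMetrics", "Connectome", function(x) {
  if (x@state != "normalized")
    stop("computeMetrics expects a normalized-state Connectome")
  w <- x@weights
  d <- shortestPathLengths(x)
  cl <- weightedClustering(x)
  eloc <- localEfficiency(x)
  L <- suppressMessages(characteristicPathLength(d))
  glob <- data.frame(
    subject_id = x@subjectID,
    clustering_C = mean(cl),
    path_length_L = as.numeric(L),
    eff_global = globalEfficiency(d),
    eff_local = mean(eloc),
    n_inf_pairs = attr(L, "excluded"),
    stringsAsFactors = FALSE
  )
  nodal <- data.frame(
    subject_id = x@subjectID,
    region_id = x@regions$id,
    region = x@regions$name,
    degree = nodeDegree(x),
    strength = nodeStrength(x),
    clustering = cl,
    betweenness = betweennessCentrality(x),
    eff_nodal = nodalEfficiency(d),
    eff_local = eloc,
    stringsAsFactors = FALSE
  )
  list(global = glob, nodal = nodal)
})
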