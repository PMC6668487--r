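# Brute-force oracles, independent of the package implementation.
# All operate on plain symmetric weight matrices; intended for n <= 7.

# toy builders ---------------------------------------------------------------

pathMatrix <- function(n, w = 1) {
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- m[i + 1, i] <- w
  m
}

ringMatrix <- function(n, w = 1) {
  m <- pathMatrix(n, w)
  m[1, n] <- m[n, 1] <- w
  m
}

completeMatrix <- function(n, w = 1) {
  m <- matrix(w, n, n)
  diag(m) <- 0
  m
}

starMatrix <- function(n, w = 1) {
  m <- matrix(0, n, n)
  m[1, -1] <- m[-1, 1] <- w
  m
}

# random connected-ish toy; weights in (0,1] with max 1 when normalized = TRUE
randomToy <- function(n, seed, p = 0.5, weighted = TRUE, normalized = TRUE) {
  set.seed(seed)
  m <- matrix(0, n, n)
  up <- which(upper.tri(m))
  on <- runif(length(up)) < p
  w <- if (weighted) runif(length(up), 0.1, 1) else rep(1, length(up))
  m[up[on]] <- w[on]
  m <- m + t(m)
  if (normalized && max(m) > 0) m <- m / max(m)
  m
}

# random integer fiber-count toy
randomCountToy <- function(n, seed, p = 0.6, maxW = 20) {
  set.seed(seed)
  m <- matrix(0, n, n)
  up <- which(upper.tri(m))
  on <- runif(length(up)) < p
  m[up[on]] <- sample.int(maxW, sum(on), replace = TRUE)
  m + t(m)
}

# oracles --------------------------------------------------------------------

# connected component sizes by hand-rolled breadth-first search
bfComponents <- function(w) {
  n <- nrow(w)
  seen <- rep(FALSE, n)
  sizes <- integer(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; size <- size + 1L
      nb <- which(w[v, ] > 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# all simple paths between i and j; returns list of (length, interior nodes)
.allSimplePaths <- function(w, i, j) {
  n <- nrow(w)
  out <- list()
  recur <- function(v, visited, len) {
    if (v == j) {
      out[[length(out) + 1]] <<- list(len = len,
                                      interior = setdiff(visited, c(i, j)))
      return(invisible())
    }
    for (u in which(w[v, ] > 0)) {
      if (u %in% visited) next
      recur(u, c(visited, u), len + 1 / w[v, u])
    }
  }
  recur(i, i, 0)
  out
}

# all-pairs shortest distances (edge length 1/w) by exhaustive path search
bfDistances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    paths <- .allSimplePaths(w, i, j)
    if (length(paths)) {
      d[i, j] <- d[j, i] <- min(vapply(paths, `[[`, numeric(1), "len"))
    }
  }
  d
}

# Onnela clustering by explicit enumeration over ordered triples
bfClustering <- function(w) {
  n <- nrow(w)
  k <- rowSums(w > 0)
  vapply(seq_len(n), function(i) {
    if (k[i] < 2) return(0)
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      s <- s + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
    }
    s / (k[i] * (k[i] - 1))
  }, numeric(1))
}

# betweenness by enumerating all geodesics of every unordered pair,
# with fractional credit to interior nodes
bfBetweenness <- function(w, tol = 1e-9) {
  n <- nrow(w)
  bc <- numeric(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    paths <- .allSimplePaths(w, i, j)
    if (!length(paths)) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    geo <- paths[lens <= min(lens) + tol]
    for (g in geo) {
      for (v in g$interior) bc[v] <- bc[v] + 1 / length(geo)
    }
  }
  bc
}

bfGlobalEfficiency <- function(w) {
  d <- bfDistances(w)
  n <- nrow(w)
  inv <- 1 / d; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# exact permutation p by full enumeration of group-A index sets
exactPermutationP <- function(values, isA, direction = "greater") {
  n <- length(values); nA <- sum(isA)
  obs <- mean(values[isA]) - mean(values[!isA])
  sets <- utils::combn(n, nA)
  diffs <- apply(sets, 2, function(ix)
    mean(values[ix]) - mean(values[-ix]))
  if (direction == "greater") mean(diffs >= obs - 1e-12)
  else mean(diffs <= obs + 1e-12)
}

# exact two-sided Fisher p by enumerating all tables with fixed margins
exactFisherP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  amin <- max(0, c1 - r2); amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(x)
    stats::dhyper(x, r1, r2, c1), numeric(1))
  pobs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}
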