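test_that("degree and strength match closed forms and direct enumeration", {
  k4 <- completeMatrix(4)
  expect_equal(nodeDegree(k4), rep(3L, 4))
  expect_equal(nodeStrength(k4), rep(3, 4))
  s4 <- starMatrix(4)
  expect_equal(nodeDegree(s4), c(3L, 1L, 1L, 1L))
  for (s in 1:5) {
    w <- randomToy(7, seed = s)
    expect_equal(nodeDegree(w), apply(w, 1, function(r) sum(r > 0)))
    expect_equal(nodeStrength(w), apply(w, 1, sum))
  }
})

test_that("Onnela clustering reproduces closed forms and the triple-enumeration oracle", {
  expect_equal(weightedClustering(completeMatrix(3)), rep(1, 3))
  expect_equal(weightedClustering(starMatrix(5)), rep(0, 5))

  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 1
  tri[1, 3] <- tri[3, 1] <- 1
  tri[2, 3] <- tri[3, 2] <- 0.5
  expect_equal(weightedClustering(tri), rep(0.5^(1 / 3), 3),
               tolerance = 1e-12)
  expect_equal(weightedClustering(tri), bfClustering(tri), tolerance = 1e-12)

  for (s in 1:6) {
    w <- randomToy(7, seed = 10 + s)
    expect_equal(weightedClustering(w), bfClustering(w), tolerance = 1e-9)
  }
})

test_that("shortest paths use inverse-weight lengths and match exhaustive enumeration", {
  p4 <- pathMatrix(4)
  d <- shortestPathLengths(p4)
  expect_equal(d[1, 4], 3)
  expect_equal(diag(d), rep(0, 4))

  # two components: cross distances infinite
  w2 <- matrix(0, 5, 5)
  w2[1, 2] <- w2[2, 1] <- 1; w2[3, 4] <- w2[4, 3] <- 1
  d2 <- shortestPathLengths(w2)
  expect_true(is.infinite(d2[1, 3]))
  expect_true(is.infinite(d2[2, 5]))

  for (s in 1:6) {
    w <- randomToy(6, seed = 20 + s, p = 0.45)
    expect_equal(shortestPathLengths(w), bfDistances(w), tolerance = 1e-9)
  }
})

test_that("characteristic path length: ring closed form, finite-pair averaging, monotone under edge addition", {
  expect_equal(as.numeric(characteristicPathLength(
    shortestPathLengths(ringMatrix(4)))), 4 / 3)
  expect_equal(as.numeric(characteristicPathLength(
    shortestPathLengths(completeMatrix(6)))), 1)

  # disconnected: infinite pairs excluded and counted
  w2 <- matrix(0, 4, 4)
  w2[1, 2] <- w2[2, 1] <- 1; w2[3, 4] <- w2[4, 3] <- 1
  L <- suppressMessages(characteristicPathLength(shortestPathLengths(w2)))
  expect_equal(as.numeric(L), 1)
  expect_equal(attr(L, "excluded"), 8)

  expect_error(characteristicPathLength(shortestPathLengths(matrix(0, 4, 4))),
               "no finite")

  # adding an edge never increases L (connected toys)
  for (s in 1:5) {
    w <- ringMatrix(6)
    set.seed(s)
    absent <- which(upper.tri(w) & w == 0)
    pick <- sample(absent, 1)
    w2 <- w; w2[pick] <- 1; w2 <- pmax(w2, t(w2))
    L1 <- as.numeric(characteristicPathLength(shortestPathLengths(w)))
    L2 <- as.numeric(characteristicPathLength(shortestPathLengths(w2)))
    expect_lte(L2, L1 + 1e-12)
  }
})

test_that("global, nodal and local efficiency match closed forms and oracle composition", {
  expect_equal(globalEfficiency(shortestPathLengths(completeMatrix(5))), 1)
  expect_equal(globalEfficiency(matrix(Inf, 4, 4) + diag(0, 4)), 0)
  expect_equal(globalEfficiency(shortestPathLengths(pathMatrix(4))), 13 / 18)

  expect_equal(nodalEfficiency(shortestPathLengths(completeMatrix(5))),
               rep(1, 5))
  expect_equal(nodalEfficiency(shortestPathLengths(pathMatrix(4)))[1],
               11 / 18)

  expect_equal(localEfficiency(completeMatrix(5)), rep(1, 5))
  expect_equal(localEfficiency(starMatrix(5)), rep(0, 5))

  # local efficiency == induced-subgraph extraction composed with the
  # (independently validated) global efficiency
  for (s in 1:5) {
    w <- randomToy(7, seed = 30 + s)
    el <- localEfficiency(w)
    oracle <- vapply(seq_len(7), function(i) {
      nb <- which(w[i, ] > 0)
      if (length(nb) < 2) return(0)
      bfGlobalEfficiency(w[nb, nb, drop = FALSE])
    }, numeric(1))
    expect_equal(el, oracle, tolerance = 1e-9)
  }

  # mean nodal efficiency is the global efficiency (algebraic identity)
  for (s in 1:5) {
    d <- shortestPathLengths(randomToy(7, seed = 40 + s, p = 0.4))
    expect_equal(mean(nodalEfficiency(d)), globalEfficiency(d),
                 tolerance = 1e-12)
  }
})

test_that("betweenness splits geodesic multiplicity fractionally and matches enumeration", {
  expect_equal(betweennessCentrality(pathMatrix(4)), c(0, 2, 2, 0))
  expect_equal(betweennessCentrality(completeMatrix(6)), rep(0, 6))
  for (s in 1:6) {
    w <- randomToy(6, seed = 50 + s, p = 0.5, weighted = FALSE)
    expect_equal(betweennessCentrality(w), bfBetweenness(w),
                 tolerance = 1e-9)
  }
  # weighted toys too
  for (s in 1:4) {
    w <- randomToy(6, seed = 60 + s, p = 0.5)
    expect_equal(betweennessCentrality(w), bfBetweenness(w),
                 tolerance = 1e-9)
  }
})

test_that("metrics are equivariant under node relabeling and invariant to weight scaling", {
  w <- randomToy(7, seed = 71, p = 0.6)
  set.seed(1); perm <- sample(7)
  wp <- w[perm, perm]
  expect_equal(weightedClustering(wp), weightedClustering(w)[perm])
  expect_equal(betweennessCentrality(wp), betweennessCentrality(w)[perm])
  expect_equal(nodeDegree(wp), nodeDegree(w)[perm])
  expect_equal(localEfficiency(wp), localEfficiency(w)[perm])
  dp <- shortestPathLengths(wp)
  expect_equal(nodalEfficiency(dp), nodalEfficiency(shortestPathLengths(w))[perm])

  # scaling all raw weights by alpha > 0 cancels after max-normalization;
  # pre-normalization distances scale by 1/alpha
  alpha <- 3.7
  expect_equal(shortestPathLengths(w * alpha), shortestPathLengths(w) / alpha)
  expect_equal(weightedClustering(w / max(w)),
               weightedClustering((alpha * w) / max(alpha * w)),
               tolerance = 1e-12)
  expect_equal(nodeDegree(w * alpha), nodeDegree(w))
  expect_equal(betweennessCentrality(w * alpha), betweennessCentrality(w))
})

test_that("weighted metrics on binary matrices equal their binary counterparts", {
  for (s in 1:4) {
    w <- randomToy(7, seed = 80 + s, p = 0.5, weighted = FALSE)
    # unit weights: path length = hop count, clustering = triangle fraction
    expect_equal(shortestPathLengths(w), bfDistances(w), tolerance = 1e-9)
    expect_equal(weightedClustering(w), bfClustering(w), tolerance = 1e-9)
    expect_equal(betweennessCentrality(w), bfBetweenness(w), tolerance = 1e-9)
    # binary clustering cross-check: fraction of closed triangles
    k <- rowSums(w)
    tri <- diag(w %*% w %*% w)
    cb <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
    expect_equal(weightedClustering(w), cb, tolerance = 1e-9)
  }
})

test_that("computeMetrics composes the parts deterministically", {
  x <- processedSubject(7)
  m1 <- computeMetrics(x)
  m2 <- computeMetrics(x)
  expect_identical(m1, m2)
  expect_equal(nrow(m1$nodal), 90)
  expect_equal(m1$global$eff_global, globalEfficiency(shortestPathLengths(x)))
  expect_equal(m1$global$clustering_C, mean(weightedClustering(x)))
  expect_equal(m1$global$eff_local, mean(m1$nodal$eff_local))
  expect_equal(mean(m1$nodal$eff_nodal), m1$global$eff_global,
               tolerance = 1e-12)
})
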