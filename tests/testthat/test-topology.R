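# FcMatrix with prescribed upper-triangle weights (lexicographic order)
fcFromWeights <- function(w, n = 10) {
  z <- matrix(0, n, n)
  idx <- which(upper.tri(z), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), ]
  z[idx] <- w
  z <- z + t(z)
  new("FcMatrix", z = z)
}

test_that("the default sparsity grid has 24 thresholds from 0.2667 to 0.4967", {
  g <- sparsityGrid()
  expect_length(g, 24)
  expect_equal(g[1], 0.2667)
  expect_equal(g[24], 0.4967)
  expect_error(sparsityGrid(0.6, 0.5), "sMin")
})

test_that("proportional thresholding keeps the right edge count with nesting", {
  set.seed(14)
  fc <- fcFromWeights(runif(45, 0.05, 1))
  a <- thresholdProportional(fc, 0.2667)
  expect_equal(sum(a) / 2, 12) # round(12.0015) = 12
  full <- thresholdProportional(fc, 1)
  expect_equal(sum(full) / 2, 45)
  prev <- a
  for (s in sparsityGrid()) {
    cur <- thresholdProportional(fc, s)
    expect_true(all(cur[prev == 1] == 1)) # nested edge sets
    prev <- cur
  }
  weak <- fcFromWeights(c(rep(0.5, 10), rep(0, 35)))
  expect_error(thresholdProportional(weak, 0.5), "positive edges")
})

test_that("minimum connected sparsity finds trees, constructed bounds and maxima", {
  # 9 strongest edges form a star spanning all 10 nodes
  w <- numeric(45)
  et <- which(upper.tri(diag(10)), arr.ind = TRUE)
  et <- et[order(et[, 1], et[, 2]), ]
  star <- et[, 1] == 1
  w[star] <- 0.9
  w[!star] <- 0.1
  expect_equal(minConnectedSparsity(fcFromWeights(w)), 9 / 45)

  # top-11 edges leave node 10 isolated; the 12th connects it
  w2 <- numeric(45)
  amongNine <- et[, 2] <= 9
  strong <- which(amongNine)[1:11]
  w2[strong] <- 0.9 - 0.01 * seq_along(strong)
  link10 <- which(et[, 1] == 9 & et[, 2] == 10)
  w2[link10] <- 0.5
  w2[w2 == 0] <- 0.05
  expect_equal(minConnectedSparsity(fcFromWeights(w2)), 12 / 45)
  expect_equal(12 / 45, 0.2667, tolerance = 2e-4)

  # group rule: the maximum over matrices
  expect_equal(
    minConnectedSparsity(list(fcFromWeights(w), fcFromWeights(w2))),
    12 / 45
  )
})

test_that("BFS distances match hand counts", {
  k4 <- matrix(1L, 4, 4)
  diag(k4) <- 0L
  expect_true(all(shortestPathLengths(k4)[upper.tri(k4)] == 1))
  path3 <- matrix(0L, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1L
  expect_equal(shortestPathLengths(path3)[1, 3], 2)
  disjoint <- matrix(0L, 4, 4)
  disjoint[1, 2] <- disjoint[2, 1] <- disjoint[3, 4] <- disjoint[4, 3] <- 1L
  expect_true(is.infinite(shortestPathLengths(disjoint)[1, 3]))
})

test_that("efficiency and clustering engine equals the brute-force oracle", {
  k4 <- matrix(1L, 4, 4)
  diag(k4) <- 0L
  path3 <- matrix(0L, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1L
  star4 <- matrix(0L, 4, 4)
  star4[1, 2:4] <- 1L
  star4[2:4, 1] <- 1L
  disjoint <- matrix(0L, 4, 4)
  disjoint[1, 2] <- disjoint[2, 1] <- disjoint[3, 4] <- disjoint[4, 3] <- 1L

  expect_equal(globalEfficiency(k4), 1)
  expect_equal(globalEfficiency(path3), 5 / 6)
  expect_equal(globalEfficiency(disjoint), 1 / 3)
  expect_equal(localEfficiency(k4), 1)
  expect_equal(localEfficiency(path3), 0)
  expect_equal(localEfficiency(star4), 0)
  expect_equal(unname(nodalEfficiency(star4, 1)), 1)
  expect_equal(unname(nodalEfficiency(star4, 2)), 2 / 3)
  expect_equal(unname(clusteringAndPathLength(k4)), c(1, 1))
  expect_equal(unname(clusteringAndPathLength(path3)), c(0, 4 / 3))
  lat <- generateNetworkTemplate("smallworld", rewireProb = 0,
    seed = 1
  )$adjacency
  expect_equal(unname(clusteringAndPathLength(lat)["C"]), 0.5)

  for (s in 1:60) {
    a <- randomConnectedGraph(sample(5:10, 1), runif(1, 0.3, 0.8), seed = s)
    expect_equal(globalEfficiency(a), oracleGlobalEff(a), tolerance = 1e-12)
    expect_equal(localEfficiency(a), oracleLocalEff(a), tolerance = 1e-12)
    expect_equal(unname(nodalEfficiency(a)), oracleNodalEff(a),
      tolerance = 1e-12
    )
    cl <- clusteringAndPathLength(a)
    expect_equal(unname(cl["C"]), mean(oracleClusteringVec(a)),
      tolerance = 1e-12
    )
    expect_equal(unname(cl["L"]), oraclePathLength(a), tolerance = 1e-12)
  }
})

test_that("degree-preserving rewiring keeps degrees and lowers lattice clustering", {
  lat20 <- as.matrix(igraph::as_adjacency_matrix(
    igraph::sample_smallworld(1, 20, 2, p = 0), sparse = FALSE
  ))
  degrees <- rowSums(lat20)
  cls <- sapply(1:100, function(s) {
    null <- rewireDegreePreserving(lat20, seed = s)
    expect_identical(rowSums(null), degrees)
    mean(oracleClusteringVec(null))
  })
  expect_lt(mean(cls), 0.5)
  null <- rewireDegreePreserving(lat20, seed = 1)
  expect_equal(sum(null), sum(lat20)) # edge count preserved
  expect_identical(rewireDegreePreserving(lat20, seed = 3),
    rewireDegreePreserving(lat20, seed = 3)
  )
})

test_that("small-worldness behaves on canonical graphs", {
  comp <- matrix(1L, 10, 10)
  diag(comp) <- 0L
  expect_identical(smallWorldness(comp, nRand = 30, seed = 1), 1)

  set.seed(60)
  ws <- as.matrix(igraph::as_adjacency_matrix(
    igraph::sample_smallworld(1, 20, 2, 0.1), sparse = FALSE
  ))
  expect_gt(smallWorldness(ws, nRand = 200, seed = 2), 1)

  # a graph drawn from its own null ensemble scores near 1
  self <- rewireDegreePreserving(ws, seed = 11)
  sig <- smallWorldness(self, nRand = 500, seed = 3)
  expect_gt(sig, 0.8)
  expect_lt(sig, 1.25)

  disconnected <- matrix(0L, 4, 4)
  disconnected[1, 2] <- disconnected[2, 1] <- 1L
  disconnected[3, 4] <- disconnected[4, 3] <- 1L
  expect_error(smallWorldness(disconnected, nRand = 10), "connected")
})

test_that("metric AUC is the threshold sum times the step", {
  expect_equal(metricAuc(rep(1, 24), 0.01), 0.24)
  set.seed(2)
  curve <- runif(24)
  expect_equal(metricAuc(3 * curve), 3 * metricAuc(curve))
  expect_error(metricAuc(numeric(0)), "empty")
})

test_that("networkMetrics aggregates curves and respects bounds", {
  set.seed(33)
  tpl <- generateNetworkTemplate("smallworld", seed = 33)
  z <- atanh(pmin(0.6 * tpl$weighted +
    abs(matrix(rnorm(100, 0, 0.05), 10, 10)), 0.99))
  z <- (z + t(z)) / 2
  diag(z) <- 0
  fc <- new("FcMatrix", z = z)
  ms <- networkMetrics(fc, nRand = 50, seed = 1, keepCurves = TRUE)
  expect_lte(ms$egAuc, ms$gridWidth)
  expect_lte(ms$elocAuc, ms$gridWidth)
  expect_true(all(ms$neAuc <= ms$gridWidth + 1e-12))
  expect_gt(ms$sigmaAuc, 0)
  expect_equal(nrow(ms$curves), 24)
  # trapezoid consistency within step * max step-to-step change
  trap <- 0.01 * (sum(ms$curves$eg) -
    (ms$curves$eg[1] + ms$curves$eg[24]) / 2)
  expect_lt(abs(ms$egAuc - trap), 0.01 * max(abs(diff(ms$curves$eg))) +
    0.01 * max(ms$curves$eg))

  # two cliques without positive cross-links cannot connect at s_min
  w <- matrix(0, 10, 10)
  w[1:5, 1:5] <- 0.9
  w[6:10, 6:10] <- 0.9
  diag(w) <- 0
  fcBad <- new("FcMatrix", z = w)
  expect_error(networkMetrics(fcBad, nRand = 10),
    "minConnectedSparsity|positive edges"
  )
})
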