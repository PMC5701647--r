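mkw <- function(m) {
  dimnames(m) <- list(paste0("n", seq_len(nrow(m))),
                      paste0("n", seq_len(nrow(m))))
  m
}

pathGraph3 <- function() {
  # A-B at w=1, B-C at w=0.5 -> lengths 1 and 2
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 0.5
  mkw(w)
}

test_that("shortest paths use reciprocal-weight edge lengths", {
  d <- shortestPaths(pathGraph3())$dist
  expect_equal(d[1, 2], 1)
  expect_equal(d[2, 3], 2)
  expect_equal(d[1, 3], 3)
  # heavy direct edge loses to a light two-hop path
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
  w[1, 3] <- w[3, 1] <- 0.2
  d2 <- shortestPaths(mkw(w))$dist
  expect_equal(d2[1, 3], 2)  # indirect (1+1) beats 1/0.2 = 5
  # two isolated nodes are mutually unreachable
  w3 <- mkw(matrix(0, 2, 2))
  sp <- shortestPaths(w3)
  expect_false(sp$reachable[1, 2])
})

test_that("shortest paths agree with igraph and the brute-force oracle", {
  set.seed(42)
  for (rep in 1:20) {
    w <- randomConnectedGraph(sample(4:7, 1), density = 0.6)
    d <- shortestPaths(w)$dist
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    dg <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(unname(d), unname(dg), tolerance = 1e-12)
    expect_equal(unname(d), unname(oracleShortestPaths(w)),
                 tolerance = 1e-12)
  }
})

test_that("Onnela clustering matches closed-form triangle cases", {
  tri <- mkw(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
  expect_equal(clusteringCoefficientW(tri), 1)
  star <- mkw(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0), c(1, 0, 0, 0),
                    c(1, 0, 0, 0)))
  expect_equal(clusteringCoefficientW(star), 0)
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
  w[1, 3] <- w[3, 1] <- 0.125
  expect_equal(clusteringCoefficientW(mkw(w)), 0.5)  # (1*1*0.125)^(1/3)
})

test_that("path length, efficiencies match hand-computed values", {
  dm <- shortestPaths(pathGraph3())
  expect_equal(characteristicPathLengthW(dm)$Lw, 2)       # (1+2+3)/3
  expect_equal(globalEfficiency(dm), (1 + 0.5 + 1 / 3) / 3)
  en <- nodalEfficiency(dm)
  expect_equal(unname(en["n2"]), (1 + 0.5) / 2)           # node B
  # complete unit-weight graph: everything is 1
  K4 <- mkw(matrix(1, 4, 4) - diag(4))
  dmK <- shortestPaths(K4)
  expect_equal(characteristicPathLengthW(dmK)$Lw, 1)
  expect_equal(globalEfficiency(dmK), 1)
  expect_equal(unname(nodalEfficiency(dmK)), rep(1, 4))
  expect_equal(localEfficiency(K4), 1)
  # star graph: no neighbor subgraph edges
  star <- mkw(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0), c(1, 0, 0, 0),
                    c(1, 0, 0, 0)))
  expect_equal(localEfficiency(star), 0)
  tri <- mkw(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
  expect_equal(localEfficiency(tri), 1)
  # empty graph: zero efficiency, path length errors
  empty <- mkw(matrix(0, 3, 3))
  expect_equal(globalEfficiency(shortestPaths(empty)), 0)
  expect_error(characteristicPathLengthW(shortestPaths(empty)),
               "empty network")
  expect_equal(unname(nodalEfficiency(shortestPaths(empty))), rep(0, 3))
})

test_that("disconnected pairs are excluded from Lw and zero in efficiencies", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1; w[3, 4] <- w[4, 3] <- 1
  dm <- shortestPaths(mkw(w))
  lp <- characteristicPathLengthW(dm)
  expect_equal(lp$Lw, 1)
  expect_equal(lp$nUnreachablePairs, 8)
  expect_equal(globalEfficiency(dm), 4 / 12)
})

test_that("metrics are scale-homogeneous in the weights", {
  set.seed(3)
  w <- randomConnectedGraph(12, density = 0.4)
  cfac <- 2.5
  dm1 <- shortestPaths(w); dm2 <- shortestPaths(w * cfac)
  expect_equal(clusteringCoefficientW(w * cfac),
               cfac * clusteringCoefficientW(w), tolerance = 1e-12)
  expect_equal(characteristicPathLengthW(dm2)$Lw,
               characteristicPathLengthW(dm1)$Lw / cfac, tolerance = 1e-12)
  expect_equal(globalEfficiency(dm2), cfac * globalEfficiency(dm1),
               tolerance = 1e-12)
  expect_equal(localEfficiency(w * cfac), cfac * localEfficiency(w),
               tolerance = 1e-12)
  expect_equal(nodalEfficiency(dm2), cfac * nodalEfficiency(dm1),
               tolerance = 1e-12)
})

test_that("efficiency metrics and Cw are bounded by 1 on normalized weights", {
  set.seed(8)
  for (rep in 1:5) {
    w <- randomConnectedGraph(15, density = 0.5)
    w <- w / max(w)
    dm <- shortestPaths(w)
    expect_lte(clusteringCoefficientW(w), 1)
    expect_lte(globalEfficiency(dm), 1)
    expect_lte(localEfficiency(w), 1)
    expect_true(all(nodalEfficiency(dm) <= 1 + 1e-12))
  }
})

test_that("adding an edge never increases characteristic path length", {
  set.seed(11)
  w <- randomConnectedGraph(10, density = 0.3)
  absent <- which(w == 0 & upper.tri(w), arr.ind = TRUE)
  lw0 <- characteristicPathLengthW(shortestPaths(w))$Lw
  for (k in seq_len(min(5, nrow(absent)))) {
    w2 <- w
    w2[absent[k, 1], absent[k, 2]] <- w2[absent[k, 2], absent[k, 1]] <- 0.5
    expect_lte(characteristicPathLengthW(shortestPaths(w2))$Lw, lw0 + 1e-12)
  }
})

test_that("joint normalization divides both hemispheres by one maximum", {
  set.seed(2)
  w <- randomConnectedGraph(10, density = 0.5)
  pair <- scaledHemiPair(w, 1.3)
  norm <- normalizeWeightsJoint(pair$L, pair$R)
  mx <- max(w * 1.3)
  expect_equal(weights(norm$L), weights(pair$L) / mx)
  expect_equal(weights(norm$R), weights(pair$R) / mx)
  expect_true(norm$L@normalized)
  # idempotent
  norm2 <- normalizeWeightsJoint(norm$L, norm$R)
  expect_equal(weights(norm2$L), weights(norm$L))
  # empty pair errors
  e <- mkw(matrix(0, 3, 3))
  pe <- scaledHemiPair(e, 1)
  expect_error(normalizeWeightsJoint(pe$L, pe$R), "empty")
})

test_that("rewiring preserves degrees, weight multiset and connectedness", {
  set.seed(21)
  for (rep in 1:25) {
    w <- randomConnectedGraph(sample(8:16, 1), density = 0.35)
    rw <- rewirePreservingDegree(w, swapsPerEdge = 10, seed = rep)
    expect_equal(colSums(rw > 0), colSums(w > 0))
    expect_equal(sort(rw[upper.tri(rw)][rw[upper.tri(rw)] > 0]),
                 sort(w[upper.tri(w)][w[upper.tri(w)] > 0]))
    g <- igraph::graph_from_adjacency_matrix(rw > 0, mode = "undirected")
    expect_true(igraph::is_connected(g))
  }
  # complete graph admits no swap
  K5 <- mkw(matrix(1, 5, 5) - diag(5))
  expect_equal(rewirePreservingDegree(K5, seed = 1), K5)
  # a reasonably dense graph is actually randomized
  set.seed(31)
  w <- randomConnectedGraph(20, density = 0.3)
  rw <- rewirePreservingDegree(w, seed = 99)
  expect_false(identical(w > 0, rw > 0))
})

test_that("small-worldness of a complete graph is exactly one", {
  K6 <- mkw(matrix(1, 6, 6) - diag(6))
  sw <- smallWorldness(K6, nNull = 10, seed = 1)
  expect_identical(sw$gamma, 1)
  expect_identical(sw$lambda, 1)
  expect_identical(sw$sigma, 1)
})

test_that("sigma is invariant under uniform weight scaling (same null seed)", {
  set.seed(5)
  w <- randomConnectedGraph(20, density = 0.25)
  s1 <- smallWorldness(w, nNull = 5, seed = 7)
  s2 <- smallWorldness(w * 3.7, nNull = 5, seed = 7)
  expect_equal(s1$sigma, s2$sigma, tolerance = 1e-10)
  expect_equal(s1$gamma, s2$gamma, tolerance = 1e-10)
})

test_that("lattice-like ring graphs have gamma well above one", {
  n <- 30
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in 1:3) {
    j <- ((i + k - 1) %% n) + 1
    w[i, j] <- w[j, i] <- 1
  }
  w <- mkw(w)
  sw <- smallWorldness(w, nNull = 10, seed = 3)
  expect_gt(sw$gamma, 1.5)
})

test_that("sparsity integration is a trapezoid average", {
  expect_equal(integrateOverSparsity(c(5, 5, 5), c(0.1, 0.2, 0.3)), 5)
  expect_equal(integrateOverSparsity(c(0, 1), c(0.10, 0.35)), 0.5)
  expect_equal(integrateOverSparsity(c(1, 0), c(0.35, 0.10)), 0.5)
  expect_equal(integrateOverSparsity(7, 0.2), 7)
  expect_error(integrateOverSparsity(c(1, 2), 0.1), "length mismatch")
})
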