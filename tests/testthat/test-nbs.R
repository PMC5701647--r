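# small aligned stacks: lists of k x k matrices
mkStack <- function(n, k, seed, f = function(w) w) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    w <- matrix(0, k, k)
    ut <- upper.tri(w)
    w[ut] <- runif(sum(ut), 0.5, 1.5)
    w <- w + t(w)
    dimnames(w) <- list(paste0("n", 1:k), paste0("n", 1:k))
    f(w)
  })
}

test_that("paired edge t statistics match the hand-computed case", {
  k <- 4
  base <- mkStack(3, k, seed = 1)
  right <- base
  left <- base
  # one edge gets differences (1, 2, 3): t = 2 / (1/sqrt(3))
  for (i in 1:3) left[[i]][1, 2] <- left[[i]][2, 1] <- right[[i]][1, 2] + i
  res <- pairedEdgeTstats(left, right)
  expect_equal(res$tMap[1, 2], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$tMap[1, 2], 3.4641016, tolerance = 1e-6)
  # all other edges have zero difference -> t = 0
  expect_equal(res$tMap[3, 4], 0)
  expect_false(res$valid[3, 4])  # zero-variance edge flagged
  # negating the differences negates the map
  res2 <- pairedEdgeTstats(right, left)
  expect_equal(res2$tMap, -res$tMap)
  # identical stacks: all-zero map
  res3 <- pairedEdgeTstats(base, base)
  expect_true(all(res3$tMap == 0))
  expect_error(pairedEdgeTstats(left[1:2], right[1:2]), "3 subjects")
})

test_that("suprathreshold components come from union-find on the kept edges", {
  t <- matrix(0, 6, 6)
  put <- function(i, j, v) t[i, j] <<- t[j, i] <<- v
  put(1, 2, 4); put(2, 3, 4); put(5, 6, 4); put(1, 4, -5)
  comps <- suprathresholdComponents(t, 3, "positive")
  expect_length(comps, 2)
  expect_equal(comps[[1]]$size, 2)   # {1-2, 2-3}
  expect_equal(comps[[1]]$nodes, c(1, 2, 3))
  expect_equal(comps[[2]]$size, 1)   # {5-6}
  neg <- suprathresholdComponents(t, 3, "negative")
  expect_equal(neg[[1]]$size, 1)
  expect_length(suprathresholdComponents(matrix(0, 4, 4), 3), 0)
  # fully suprathreshold 45-node graph: one component of 990 edges
  full <- matrix(10, 45, 45); diag(full) <- 0
  cf <- suprathresholdComponents(full, 3)
  expect_length(cf, 1)
  expect_equal(cf[[1]]$size, 990)
  # cross-check component membership against igraph on random maps
  set.seed(9)
  for (rep in 1:10) {
    tm <- matrix(0, 12, 12)
    ut <- upper.tri(tm)
    tm[ut] <- rnorm(sum(ut), sd = 3)
    tm <- tm + t(tm)
    comps <- suprathresholdComponents(tm, 3, "positive")
    keep <- which(tm > 3 & ut, arr.ind = TRUE)
    if (nrow(keep) == 0) { expect_length(comps, 0); next }
    g <- igraph::graph_from_edgelist(keep, directed = FALSE)
    memb <- igraph::components(g)$membership
    expect_equal(sort(vapply(comps, `[[`, 0, "size"), decreasing = TRUE),
                 sort(as.vector(table(memb[keep[, 1]])), decreasing = TRUE))
  }
})

test_that("exhaustive paired NBS equals the brute-force sign-flip oracle", {
  ns <- 8; k <- 10
  right <- mkStack(ns, k, seed = 3)
  left <- lapply(seq_len(ns), function(i) {
    w <- right[[i]]
    # a connected 3-edge boost so an observed component exists
    for (e in list(c(1, 2), c(2, 3), c(3, 4)))
      w[e[1], e[2]] <- w[e[2], e[1]] <- w[e[1], e[2]] * 1.6 + 0.3 * i / ns
    w
  })
  res <- nbsPaired(left, right, tThreshold = 2.0, seed = 1,
                   exhaustive = TRUE)
  expect_equal(res@nPerm, 256L)
  orc <- oracleNbsExhaustive(left, right, thr = 2.0)
  obs <- res@components$positive
  expect_gt(length(obs), 0)
  expect_equal(obs[[1]]$size, orc$obsPos)
  expect_equal(obs[[1]]$p, orc$pPos(obs[[1]]$size), tolerance = 1e-12)
  for (co in res@components$negative)
    expect_equal(co$p, orc$pNeg(co$size), tolerance = 1e-12)
})

test_that("permutation p is seed-reproducible and relabeling-invariant", {
  ns <- 10; k <- 8
  right <- mkStack(ns, k, seed = 5)
  left <- lapply(right, function(w) w * 1.15)
  r1 <- nbsPaired(left, right, tThreshold = 2.5, nPerm = 200, seed = 42)
  r2 <- nbsPaired(left, right, tThreshold = 2.5, nPerm = 200, seed = 42)
  expect_identical(r1@nullMaxSizes, r2@nullMaxSizes)
  expect_identical(
    vapply(r1@components$positive, `[[`, 0, "p"),
    vapply(r2@components$positive, `[[`, 0, "p"))
  # permuting the subject order leaves the p-values unchanged
  perm <- sample(ns)
  r3 <- nbsPaired(left[perm], right[perm], tThreshold = 2.5, nPerm = 200,
                  seed = 42)
  expect_identical(
    vapply(r1@components$positive, `[[`, 0, "p"),
    vapply(r3@components$positive, `[[`, 0, "p"))
})

test_that("identical stacks report no suprathreshold connectivity", {
  base <- mkStack(5, 6, seed = 2)
  res <- nbsPaired(base, base, tThreshold = 3, nPerm = 20, seed = 1)
  expect_length(res@components$positive, 0)
  expect_length(res@components$negative, 0)
  expect_output(show(res), "no suprathreshold connectivity")
  expect_error(nbsPaired(base, base, tThreshold = 0, nPerm = 10), "positive")
})

test_that("a planted lateralized component is recovered with low p", {
  nt <- aal90NodeTable()
  ring <- data.frame(i = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 1),
                     j = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 10),
                     delta = pairedEffectDelta(1.2, 0.1))
  spec <- asymmetrySpec(edgeSubnetwork = ring)
  subs <- lapply(1:25, function(i)
    splitHemispheres(simulateStructuralConnectome(
      nt, structuralParams(noiseSd = 0.1), spec, seed = 1000 + i,
      templateSeed = 999), nt))
  res <- nbsPaired(lapply(subs, `[[`, "L"), lapply(subs, `[[`, "R"),
                   tThreshold = 3, nPerm = 300, seed = 9)
  expect_gt(length(res@components$positive), 0)
  top <- res@components$positive[[1]]
  expect_lt(top$p, 0.05)
  planted <- paste(pmin(ring$i, ring$j), pmax(ring$i, ring$j))
  found <- paste(top$edges[, 1], top$edges[, 2])
  expect_gte(mean(planted %in% found), 0.8)
})
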