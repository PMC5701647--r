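# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# brute-force all-pairs shortest paths by exhaustive simple-path enumeration
# on reciprocal-weight lengths (feasible for <= ~7 nodes)
oracleShortestPaths <- function(w) {
  n <- nrow(w)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  for (s in seq_len(n)) {
    rec <- function(v, visited, acc) {
      for (u in which(w[v, ] > 0)) {
        if (visited[u]) next
        d <- acc + 1 / w[v, u]
        if (d < best[s, u]) best[s, u] <<- d
        vis2 <- visited; vis2[u] <- TRUE
        rec(u, vis2, d)
      }
    }
    vis <- logical(n); vis[s] <- TRUE
    rec(s, vis, 0)
  }
  best
}

# random connected weighted graph on n nodes (labels V1..Vn)
randomConnectedGraph <- function(n, density = 0.5) {
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    m <- sum(ut)
    vals <- ifelse(stats::runif(m) < density, stats::runif(m, 0.1, 2), 0)
    w[ut] <- vals
    w <- w + t(w)
    dimnames(w) <- list(paste0("V", 1:n), paste0("V", 1:n))
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    if (igraph::is_connected(g)) return(w)
  }
}

# Benjamini-Hochberg step-up rejection, straight from the definition
oracleBhReject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  crit <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(crit)) rej[o[seq_len(max(crit))]] <- TRUE
  rej
}

# ANCOVA hemisphere F by explicit normal equations (full vs reduced RSS)
oracleAncovaF <- function(left, right, gender) {
  n <- length(left)
  y <- c(left, right)
  hemi <- rep(c(0, 1), each = n)
  g <- as.numeric(factor(rep(as.character(gender), 2))) - 1
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  rssF <- rss(cbind(1, hemi, g))
  rssR <- rss(cbind(1, g))
  dfden <- 2 * n - 3
  (rssR - rssF) / (rssF / dfden)
}

# exhaustive paired-NBS oracle: enumerate all 2^n sign flips with naive
# per-edge t tests and igraph components
oracleNbsExhaustive <- function(leftMats, rightMats, thr) {
  ns <- length(leftMats)
  nn <- nrow(leftMats[[1]])
  ut <- which(upper.tri(leftMats[[1]]), arr.ind = TRUE)
  d <- t(vapply(seq_len(ns), function(i)
    (leftMats[[i]] - rightMats[[i]])[ut], numeric(nrow(ut))))
  tOf <- function(dd) {
    apply(dd, 2, function(col) {
      s <- stats::sd(col)
      if (s < 1e-12) return(0)
      mean(col) / (s / sqrt(length(col)))
    })
  }
  validv <- apply(d, 2, stats::sd) > 1e-12
  maxComp <- function(tv, sgn) {
    keep <- if (sgn > 0) tv > thr else tv < -thr
    keep <- keep & validv
    if (!any(keep)) return(0L)
    g <- igraph::graph_from_edgelist(ut[keep, , drop = FALSE],
                                     directed = FALSE)
    memb <- igraph::components(g)$membership
    max(table(memb[ut[keep, 1]]))  # edge count per component
  }
  allSigns <- as.matrix(expand.grid(rep(list(c(1, -1)), ns)))
  nullPos <- integer(nrow(allSigns))
  nullNeg <- integer(nrow(allSigns))
  for (k in seq_len(nrow(allSigns))) {
    tv <- tOf(allSigns[k, ] * d)
    nullPos[k] <- maxComp(tv, 1)
    nullNeg[k] <- maxComp(tv, -1)
  }
  tvObs <- tOf(d)
  list(
    obsPos = maxComp(tvObs, 1), obsNeg = maxComp(tvObs, -1),
    pPos = function(size) mean(nullPos >= size),
    pNeg = function(size) mean(nullNeg >= size))
}

# small hemisphere-pair fixture: right block w, left block c * w
scaledHemiPair <- function(w, cfac, modality = "structural") {
  mk <- function(mat, h) new("HemiNetwork", weights = mat, subjectId = "t",
                             modality = modality, hemisphere = h,
                             sparsity = NA_real_, normalized = FALSE,
                             flags = list())
  list(L = mk(w * cfac, "L"), R = mk(w, "R"))
}
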