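#' Joint max-weight normalization of a hemisphere pair
#'
#' Divides both hemispheric weight matrices by the single maximum weight over
#' the two networks.  Joint (rather than per-network) normalization bounds the
#' weighted clustering coefficient in [0, 1] without cancelling the
#' between-hemisphere weight asymmetry under study.  Idempotent.
#'
#' @param left,right \linkS4class{HemiNetwork}s of one subject and modality.
#' @return List with elements \code{L} and \code{R} (normalized networks).
#' @export
normalizeWeightsJoint <- function(left, right) {
  .stopifnot2(identical(modality(left), modality(right)),
              "hemispheres must share a modality")
  mx <- max(weights(left), weights(right))
  if (mx == 0) stop("both networks are empty")
  mk <- function(hn) {
    .HemiNetwork(weights(hn) / mx, subjectId(hn), modality(hn),
                 hemisphere(hn), sparsity = sparsity(hn), normalized = TRUE,
                 flags = hn@flags)
  }
  list(L = mk(left), R = mk(right))
}

.weightsOf <- function(x) if (is(x, "HemiNetwork")) weights(x) else x

#' All-pairs shortest path lengths
#'
#' Edge length is the reciprocal of the edge weight (stronger connections are
#' shorter); absent edges have infinite length unless an indirect path
#' exists.  Disconnection is represented (infinite distance), not an error.
#'
#' @param hn a \linkS4class{HemiNetwork} or a weight matrix.
#' @return List with \code{dist} (numeric matrix, \code{Inf} for unreachable
#'   pairs) and \code{reachable} (logical matrix, diagonal \code{TRUE}).
#' @examples
#' w <- rbind(c(0, 1, 0), c(1, 0, 0.5), c(0, 0.5, 0))
#' shortestPaths(w)$dist
#' @export
shortestPaths <- function(hn) {
  w <- .weightsOf(hn)
  .stopifnot2(all(w >= 0), "weights must be nonnegative")
  d <- .spDist(w)
  list(dist = d, reachable = is.finite(d))
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per-node geometric-mean triangle intensity
#' \eqn{\frac{1}{k_i(k_i-1)} \sum_{j,k} (w_{ij} w_{jk} w_{ki})^{1/3}}
#' summed over ordered neighbor pairs, averaged over all N nodes.  Nodes with
#' degree < 2 contribute 0.  Lies in [0, 1] when weights are max-normalized.
#'
#' @param hn a \linkS4class{HemiNetwork} or weight matrix (weights <= 1 for
#'   the [0, 1] bound).
#' @return Scalar C_w.
#' @export
clusteringCoefficientW <- function(hn) {
  w <- .weightsOf(hn)
  n <- nrow(w)
  k <- colSums(w > 0)
  w3 <- w^(1 / 3)
  tri <- diag(w3 %*% w3 %*% w3)  # sum over ordered pairs (j, k)
  term <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  mean(term)
}

#' Weighted characteristic path length
#'
#' Mean shortest path length over reachable ordered pairs (equivalently
#' unordered, by symmetry).  Unreachable pairs are excluded from the average
#' and counted.
#'
#' @param dm distance structure from \code{\link{shortestPaths}}.
#' @return List with \code{Lw} and \code{nUnreachablePairs} (ordered pairs).
#' @export
characteristicPathLengthW <- function(dm) {
  d <- dm$dist
  off <- row(d) != col(d)
  fin <- off & is.finite(d)
  if (!any(fin)) stop("empty network")
  list(Lw = mean(d[fin]), nUnreachablePairs = sum(off & !is.finite(d)))
}

#' Global efficiency
#'
#' Mean of inverse shortest path lengths over all ordered pairs, with
#' \code{1/Inf = 0} for unreachable pairs (full \code{N(N-1)} denominator).
#'
#' @param dm distance structure from \code{\link{shortestPaths}}.
#' @return Scalar E_global.
#' @export
globalEfficiency <- function(dm) {
  d <- dm$dist
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbors (edge weights retained), averaged over all N nodes; nodes with
#' fewer than 2 neighbors contribute 0.
#'
#' @param hn a \linkS4class{HemiNetwork} or weight matrix.
#' @return Scalar E_local.
#' @export
localEfficiency <- function(hn) {
  w <- .weightsOf(hn)
  n <- nrow(w)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    globalEfficiency(list(dist = .spDist(w[nb, nb, drop = FALSE])))
  }, numeric(1))
  mean(vals)
}

#' Nodal efficiency
#'
#' \eqn{E_{nodal}(i) = \frac{1}{N-1} \sum_{j \ne i} 1 / L_{ij}}, the inverse
#' harmonic mean of shortest path lengths from node i to all others, with
#' \code{1/Inf = 0}; an isolated node scores 0.
#'
#' @param dm distance structure from \code{\link{shortestPaths}}.
#' @return Named numeric vector, one value per node.
#' @export
nodalEfficiency <- function(dm) {
  d <- dm$dist
  n <- nrow(d)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  diag(inv) <- 0
  out <- rowSums(inv) / (n - 1)
  names(out) <- rownames(d)
  out
}

# Maslov-Sneppen double-edge swaps on a weight matrix; weights travel with
# their edges; binary degree sequence preserved exactly.  Returns the weight
# matrix (connectedness handled by the caller).
.rewireOnce <- function(w, swapsPerEdge) {
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 2) return(w)
  ei <- ut[, 1L]; ej <- ut[, 2L]
  ew <- w[ut]
  adj <- w > 0
  attempts <- as.integer(swapsPerEdge) * m
  r1 <- sample.int(m, attempts, replace = TRUE)
  r2 <- sample.int(m, attempts, replace = TRUE)
  flip <- stats::runif(attempts) < 0.5
  for (t in seq_len(attempts)) {
    e1 <- r1[t]; e2 <- r2[t]
    if (e1 == e2) next
    a <- ei[e1]; b <- ej[e1]
    if (flip[t]) { c <- ej[e2]; d <- ei[e2] } else { c <- ei[e2]; d <- ej[e2] }
    # propose (a, d) and (c, b)
    if (a == d || c == b) next
    if (adj[a, d] || adj[c, b]) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c, d] <- adj[d, c] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    adj[c, b] <- adj[b, c] <- TRUE
    ei[e1] <- a; ej[e1] <- d
    ei[e2] <- c; ej[e2] <- b
  }
  out <- matrix(0, n, n, dimnames = dimnames(w))
  out[cbind(ei, ej)] <- ew
  out[cbind(ej, ei)] <- ew
  out
}

#' Degree-preserving rewiring null model
#'
#' Randomizes a weighted network by repeated double-edge swaps: two edges are
#' chosen at random and their endpoints exchanged, rejecting swaps that would
#' create a self-loop or multi-edge.  Weights travel with their edges, so the
#' binary degree sequence and the multiset of edge weights are preserved
#' exactly.  If the input was connected and the rewired graph is not, the
#' full rewiring is retried up to \code{maxRetries} times; the final attempt
#' is returned with a \code{disconnected} flag if none succeeds.  Inputs with
#' no admissible swap (e.g. a complete graph) are returned unchanged.
#'
#' @param hn a \linkS4class{HemiNetwork} or weight matrix.
#' @param swapsPerEdge attempted swaps per edge (default 10).
#' @param seed integer RNG seed.
#' @param maxRetries connectedness retries (default 10).
#' @return Object of the same kind as \code{hn} (flag
#'   \code{disconnected} set on failure; for matrix input the flag is an
#'   attribute).
#' @export
rewirePreservingDegree <- function(hn, swapsPerEdge = 10L, seed = 1L,
                                   maxRetries = 10L) {
  w <- .weightsOf(hn)
  set.seed(seed)
  wasConnected <- .isConnected(w > 0)
  disconnected <- FALSE
  for (att in seq_len(max(1L, maxRetries))) {
    out <- .rewireOnce(w, swapsPerEdge)
    if (!wasConnected || .isConnected(out > 0)) { disconnected <- FALSE; break }
    disconnected <- TRUE
  }
  if (is(hn, "HemiNetwork")) {
    flags <- hn@flags
    if (disconnected) flags$disconnected <- TRUE
    .HemiNetwork(out, subjectId(hn), modality(hn), hemisphere(hn),
                 sparsity = sparsity(hn), normalized = hn@normalized,
                 flags = flags)
  } else {
    if (disconnected) attr(out, "disconnected") <- TRUE
    out
  }
}

#' Small-worldness against degree-preserving nulls
#'
#' Computes \code{gamma = C_w / C_w_rand}, \code{lambda = L_w / L_w_rand} and
#' \code{sigma = gamma / lambda}, where the null values are means over
#' \code{nNull} degree-preserving rewired networks (weights traveling with
#' edges).  A complete graph admits no swap, so its null equals itself and
#' sigma is exactly 1.
#'
#' @param hn a \linkS4class{HemiNetwork} or weight matrix.
#' @param nNull number of null networks (>= 1; 100 is the conventional
#'   choice).
#' @param seed integer RNG seed for the null stream.
#' @param swapsPerEdge passed to the rewiring.
#' @return List with \code{Cw}, \code{Lw}, \code{CwRand}, \code{LwRand},
#'   \code{gamma}, \code{lambda}, \code{sigma}.
#' @export
smallWorldness <- function(hn, nNull = 100L, seed = 1L, swapsPerEdge = 10L) {
  .stopifnot2(nNull >= 1, "nNull must be >= 1")
  w <- .weightsOf(hn)
  cw <- clusteringCoefficientW(w)
  lw <- characteristicPathLengthW(shortestPaths(w))$Lw
  cr <- numeric(nNull)
  lr <- numeric(nNull)
  for (b in seq_len(nNull)) {
    nw <- rewirePreservingDegree(w, swapsPerEdge = swapsPerEdge,
                                 seed = .deriveSeed(seed, b))
    cr[b] <- clusteringCoefficientW(nw)
    lr[b] <- characteristicPathLengthW(shortestPaths(nw))$Lw
  }
  cwr <- mean(cr); lwr <- mean(lr)
  if (cwr == 0 || lwr == 0) stop("degenerate null")
  list(Cw = cw, Lw = lw, CwRand = cwr, LwRand = lwr,
       gamma = cw / cwr, lambda = lw / lwr,
       sigma = (cw / cwr) / (lw / lwr))
}

#' Integrate a metric over the sparsity range
#'
#' Trapezoidal area under the metric-versus-sparsity curve divided by the
#' range (i.e. the average value over the range); a single level returns its
#' value.  Levels are sorted internally.
#'
#' @param values metric values, one per sparsity level.
#' @param levels sparsity levels.
#' @return Scalar integrated metric.
#' @export
integrateOverSparsity <- function(values, levels) {
  .stopifnot2(length(values) == length(levels), "length mismatch")
  .stopifnot2(length(values) >= 1, "need at least one level")
  .stopifnot2(all(is.finite(values)), "values must be finite")
  if (length(values) == 1) return(values[[1]])
  o <- order(levels)
  x <- levels[o]; y <- values[o]
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  area / (max(x) - min(x))
}

#' All global and regional metrics of one hemispheric network
#'
#' Convenience wrapper computing C_w, L_w, E_global, E_local, E_nodal and,
#' optionally, the small-world indices (gamma, lambda, sigma) for a single
#' (already normalized) network.
#'
#' @param hn a \linkS4class{HemiNetwork}.
#' @param nNull rewired nulls for sigma; 0 skips the small-world indices.
#' @param seed RNG seed for the null stream.
#' @return Named list: \code{Cw}, \code{Lw}, \code{Eglobal}, \code{Elocal},
#'   \code{Enodal} (named vector), \code{nUnreachablePairs}, and when
#'   requested \code{gamma}, \code{lambda}, \code{sigma}.
#' @export
hemiMetrics <- function(hn, nNull = 100L, seed = 1L) {
  dm <- shortestPaths(hn)
  lp <- characteristicPathLengthW(dm)
  out <- list(Cw = clusteringCoefficientW(hn),
              Lw = lp$Lw,
              Eglobal = globalEfficiency(dm),
              Elocal = localEfficiency(hn),
              Enodal = nodalEfficiency(dm),
              nUnreachablePairs = lp$nUnreachablePairs)
  if (nNull > 0) {
    sw <- smallWorldness(hn, nNull = nNull, seed = seed)
    out$gamma <- sw$gamma; out$lambda <- sw$lambda; out$sigma <- sw$sigma
  }
  out
}

#' Sparsity-integrated metrics of a functional hemispheric network
#'
#' Thresholds the (unthresholded, normalized) network over the sparsity grid,
#' computes every metric at each level, and integrates each metric over the
#' range (trapezoid average).  Sigma is computed per level against rewired
#' nulls and then integrated.
#'
#' @param hn unthresholded \linkS4class{HemiNetwork}.
#' @param sMin,sMax,step sparsity grid (defaults 0.10--0.35 by 0.01).
#' @param nNull rewired nulls per level for sigma; 0 skips sigma.
#' @param seed RNG seed.
#' @return As \code{\link{hemiMetrics}}, each entry integrated over the grid,
#'   plus \code{nUnreachablePairs} (maximum over levels).
#' @export
integratedMetrics <- function(hn, sMin = 0.10, sMax = 0.35, step = 0.01,
                              nNull = 100L, seed = 1L) {
  series <- sparsitySeries(hn, sMin, sMax, step)
  levels <- as.numeric(names(series))
  per <- lapply(seq_along(series), function(k)
    hemiMetrics(series[[k]], nNull = nNull, seed = .deriveSeed(seed, k)))
  pull <- function(f) vapply(per, `[[`, numeric(1), f)
  out <- list(Cw = integrateOverSparsity(pull("Cw"), levels),
              Lw = integrateOverSparsity(pull("Lw"), levels),
              Eglobal = integrateOverSparsity(pull("Eglobal"), levels),
              Elocal = integrateOverSparsity(pull("Elocal"), levels))
  en <- vapply(per, `[[`, numeric(length(per[[1]]$Enodal)), "Enodal")
  out$Enodal <- apply(en, 1, integrateOverSparsity, levels = levels)
  out$nUnreachablePairs <- max(vapply(per, `[[`, numeric(1),
                                      "nUnreachablePairs"))
  if (nNull > 0) {
    out$gamma <- integrateOverSparsity(pull("gamma"), levels)
    out$lambda <- integrateOverSparsity(pull("lambda"), levels)
    out$sigma <- integrateOverSparsity(pull("sigma"), levels)
  }
  out
}
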