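# Internal numerical helpers shared across modules.

# All-pairs shortest path lengths on reciprocal-weight edge lengths
# (L_ij = 1/w_ij, absent edge = Inf).  Vectorized Floyd-Warshall; for the
# network sizes handled here (<= 90 nodes) a dense pass is faster than
# per-call graph construction.
.spDist <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- d[, k] + rep(d[k, ], each = n)
    upd <- dk < d
    if (any(upd)) d[upd] <- dk[upd]
  }
  d
}

# Connectivity of the binary graph underlying a weight matrix.
.isConnected <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(TRUE)
  seen <- logical(n)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# Deterministic per-unit seed derivation from a master seed.  Plain affine
# hash kept below 2^31 so it is a valid set.seed() argument.
.deriveSeed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (i in idx) s <- (s * 69069 + as.double(i) * 30011 + 1013) %% 2147483647
  as.integer(s)
}

# Union-find over n nodes; edges is a 2-column matrix.  Returns component
# membership for each edge's root and sizes by edge count.
.edgeComponents <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  m <- nrow(edges)
  for (e in seq_len(m)) {
    ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
    if (ra != rb) parent[ra] <- rb
  }
  # returns root id per edge
  vapply(seq_len(m), function(e) find(edges[e, 1L]), integer(1))
}

# round half away from zero (edge-count rule for sparsity thresholding)
.roundHalfUp <- function(x) floor(x + 0.5)

.stopifnot2 <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
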