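# stack coercion: list of HemiNetwork / list of matrices / 3-d array
# -> n x nEdge matrix of upper-triangle edge weights, plus edge index table
.stackEdges <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3) {
    stack <- lapply(seq_len(dim(stack)[1]), function(i) stack[i, , ])
  }
  mats <- lapply(stack, .weightsOf)
  n <- nrow(mats[[1]])
  labs <- rownames(mats[[1]])
  for (m in mats)
    if (!identical(dim(m), dim(mats[[1]])) ||
        !identical(rownames(m), labs))
      stop("stacks are not homotopically aligned")
  ut <- which(upper.tri(mats[[1]]), arr.ind = TRUE)
  x <- t(vapply(mats, function(m) m[ut], numeric(nrow(ut))))
  list(x = x, edges = ut, n = n, labels = labs)
}

#' Edge-wise paired t statistics between hemispheres
#'
#' For each homotopic edge, the paired t statistic of the left-minus-right
#' weight difference across subjects: \code{t = mean(d) / (sd(d)/sqrt(n))}.
#' Edges whose differences have zero variance get t = 0 when the mean is also
#' zero and a large signed sentinel (1e6) otherwise; such edges are flagged
#' and excluded from component formation by \code{\link{nbsPaired}}.
#'
#' @param leftStack,rightStack aligned stacks of hemispheric networks: lists
#'   of \linkS4class{HemiNetwork}s or matrices, or \code{n x 45 x 45} arrays.
#' @return List with \code{tMap} (matrix), \code{valid} (logical matrix,
#'   FALSE where variance was zero) and \code{n} (subjects).
#' @export
pairedEdgeTstats <- function(leftStack, rightStack) {
  sl <- .stackEdges(leftStack)
  sr <- .stackEdges(rightStack)
  if (!identical(sl$n, sr$n) || !identical(sl$labels, sr$labels) ||
      nrow(sl$x) != nrow(sr$x))
    stop("stacks are not homotopically aligned")
  ns <- nrow(sl$x)
  .stopifnot2(ns >= 3, "need at least 3 subjects")
  d <- sl$x - sr$x
  mu <- colMeans(d)
  sdd <- apply(d, 2, stats::sd)
  tv <- ifelse(sdd > 0, mu / (sdd / sqrt(ns)),
               ifelse(mu == 0, 0, sign(mu) * 1e6))
  nn <- sl$n
  tMap <- matrix(0, nn, nn, dimnames = list(sl$labels, sl$labels))
  tMap[sl$edges] <- tv
  tMap <- tMap + t(tMap)
  valid <- matrix(TRUE, nn, nn, dimnames = dimnames(tMap))
  valid[sl$edges] <- sdd > 0
  valid <- valid & t(valid)
  list(tMap = tMap, valid = valid, n = ns)
}

#' Suprathreshold connected components
#'
#' Keeps edges with \code{t > tThreshold} (or \code{t < -tThreshold} for the
#' opposite tail) and returns the connected components of the resulting
#' graph, sized by edge count and sorted by decreasing size.
#'
#' @param tMap symmetric matrix of edge statistics.
#' @param tThreshold component-forming threshold (> 0).
#' @param sign \code{"positive"} (left > right for a left-minus-right t map)
#'   or \code{"negative"}.
#' @param valid optional logical matrix; edges with \code{FALSE} are excluded.
#' @return List of components, each with \code{edges} (2-column index
#'   matrix), \code{nodes}, and \code{size} (edge count).  Empty list when no
#'   edge is suprathreshold.
#' @export
suprathresholdComponents <- function(tMap, tThreshold,
                                     sign = c("positive", "negative"),
                                     valid = NULL) {
  .stopifnot2(tThreshold > 0, "tThreshold must be positive")
  sign <- match.arg(sign)
  n <- nrow(tMap)
  keep <- if (sign == "positive") tMap > tThreshold else tMap < -tThreshold
  if (!is.null(valid)) keep <- keep & valid
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  edges <- which(keep, arr.ind = TRUE)
  if (nrow(edges) == 0) return(list())
  roots <- .edgeComponents(n, edges)
  comps <- lapply(split(seq_len(nrow(edges)), roots), function(idx) {
    e <- edges[idx, , drop = FALSE]
    list(edges = unname(e), nodes = sort(unique(as.vector(e))),
         size = nrow(e))
  })
  comps <- unname(comps)
  comps[order(-vapply(comps, `[[`, 0, "size"))]
}

# max suprathreshold component size per tail from an edge-wise t vector
.maxCompSize <- function(tv, edges, n, thr, validv) {
  out <- c(positive = 0L, negative = 0L)
  for (s in c(1, -1)) {
    keep <- if (s > 0) tv > thr else tv < -thr
    keep <- keep & validv
    if (!any(keep)) next
    e <- edges[keep, , drop = FALSE]
    roots <- .edgeComponents(n, e)
    out[if (s > 0) "positive" else "negative"] <-
      max(tabulate(match(roots, unique(roots))))
  }
  out
}

#' Paired network-based statistic
#'
#' Localizes lateralized connections: edge-wise paired t statistics between
#' homotopically aligned left and right networks, suprathreshold connected
#' components for each tail, and a permutation null of the maximal component
#' size obtained by randomly swapping each subject's left/right labels
#' (independent fair coin per subject; in exhaustive mode all \code{2^n}
#' sign patterns are enumerated).  The corrected p-value of a component of
#' size s is \code{(1 + #[null >= s]) / (1 + nPerm)} (exact proportion over
#' all patterns in exhaustive mode).  Each tail is compared against its own
#' null distribution.  Zero-variance edges are excluded from component
#' formation.
#'
#' @param leftStack,rightStack aligned stacks (see
#'   \code{\link{pairedEdgeTstats}}).
#' @param tThreshold component-forming threshold (> 0); NBS inference is
#'   threshold-dependent, so the value is always recorded in the result.
#' @param nPerm number of permutations (default 5000; ignored when
#'   \code{exhaustive}).
#' @param seed integer RNG seed.
#' @param exhaustive enumerate all \code{2^n} label swaps (feasible for small
#'   cohorts); yields the exact permutation p.
#' @return An \linkS4class{NBSResult}.
#' @examples
#' cb <- simulateCohort(6, seed = 2)
#' hemi <- lapply(cb$subjects, function(s) splitHemispheres(s$structural))
#' res <- nbsPaired(lapply(hemi, `[[`, "L"), lapply(hemi, `[[`, "R"),
#'                  tThreshold = 3, nPerm = 50, seed = 1)
#' res
#' @export
nbsPaired <- function(leftStack, rightStack, tThreshold = 3.0,
                      nPerm = 5000L, seed = 1L, exhaustive = FALSE) {
  .stopifnot2(tThreshold > 0, "tThreshold must be positive")
  sl <- .stackEdges(leftStack)
  sr <- .stackEdges(rightStack)
  if (!identical(sl$labels, sr$labels) || nrow(sl$x) != nrow(sr$x))
    stop("stacks are not homotopically aligned")
  ns <- nrow(sl$x)
  .stopifnot2(ns >= 3, "need at least 3 subjects")
  d <- sl$x - sr$x
  ss <- colSums(d^2)  # invariant under sign flips
  nn <- sl$n
  edges <- sl$edges

  tFrom <- function(s) {
    mu <- as.vector(crossprod(s, d)) / ns
    va <- (ss - ns * mu^2) / (ns - 1)
    ifelse(va > 1e-24, mu / sqrt(va / ns),
           ifelse(mu == 0, 0, sign(mu) * 1e6))
  }

  sObs <- rep(1, ns)
  tvObs <- tFrom(sObs)
  validv <- {
    mu <- colMeans(d); va <- (ss - ns * mu^2) / (ns - 1)
    va > 1e-24
  }
  tMap <- matrix(0, nn, nn, dimnames = list(sl$labels, sl$labels))
  tMap[edges] <- tvObs
  tMap <- tMap + t(tMap)
  validM <- matrix(TRUE, nn, nn, dimnames = dimnames(tMap))
  validM[edges] <- validv
  validM <- validM & t(validM)

  compPos <- suprathresholdComponents(tMap, tThreshold, "positive", validM)
  compNeg <- suprathresholdComponents(tMap, tThreshold, "negative", validM)

  if (exhaustive) {
    .stopifnot2(ns <= 20, "exhaustive mode limited to n <= 20 subjects")
    nPerm <- as.integer(2^ns)
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), ns)))
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(1, -1), as.integer(nPerm) * ns, replace = TRUE),
                    nrow = as.integer(nPerm))
  }
  nullMax <- matrix(0L, nrow(signs), 2,
                    dimnames = list(NULL, c("positive", "negative")))
  for (p in seq_len(nrow(signs))) {
    tv <- tFrom(signs[p, ])
    # zero-variance exclusion re-derived per permutation (|d| is fixed, so
    # the observed mask applies except when the flipped mean hits zero)
    nullMax[p, ] <- .maxCompSize(tv, edges, nn, tThreshold, validv)
  }
  pFor <- function(size, tail) {
    if (exhaustive) mean(nullMax[, tail] >= size)
    else (1 + sum(nullMax[, tail] >= size)) / (1 + nrow(signs))
  }
  compPos <- lapply(compPos, function(co) {
    co$p <- pFor(co$size, "positive"); co
  })
  compNeg <- lapply(compNeg, function(co) {
    co$p <- pFor(co$size, "negative"); co
  })
  new("NBSResult", tMap = tMap, tThreshold = tThreshold,
      components = list(positive = compPos, negative = compNeg),
      nullMaxSizes = nullMax, nPerm = as.integer(nrow(signs)),
      exhaustive = exhaustive, seed = as.integer(seed))
}
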