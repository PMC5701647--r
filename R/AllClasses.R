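.checkWeightMatrix <- function(w, tol = 1e-8) {
  if (!is.matrix(w) || !is.numeric(w))
    return("weights must be a numeric matrix")
  if (nrow(w) != ncol(w))
    return(sprintf("weights must be square (got %d x %d)", nrow(w), ncol(w)))
  if (any(!is.finite(w)))
    return("weights contain non-finite values")
  if (any(w < 0))
    return("weights must be nonnegative")
  if (any(abs(w - t(w)) > tol)) {
    bad <- which(abs(w - t(w)) > tol, arr.ind = TRUE)[1, ]
    return(sprintf("weights not symmetric at (%d, %d)", bad[1], bad[2]))
  }
  if (any(diag(w) != 0))
    return("diagonal must be zero")
  TRUE
}

#' Whole-brain weighted connectome
#'
#' A symmetric, nonnegative, zero-diagonal weighted adjacency matrix over the
#' 90 AAL regions (or any even number of bilaterally paired regions), for one
#' subject and one modality.  Structural weights are streamline densities
#' (streamline count divided by the summed volumes of the two regions);
#' functional weights are Fisher r-to-z transformed positive Pearson
#' correlations.
#'
#' @slot weights numeric matrix, symmetric, nonnegative, zero diagonal; row
#'   and column names are region labels matching a node table.
#' @slot subjectId character scalar.
#' @slot modality \code{"structural"} or \code{"functional"}.
#' @export
setClass("ConnectomeMatrix",
  representation(weights = "matrix", subjectId = "character",
                 modality = "character"),
  validity = function(object) {
    msg <- .checkWeightMatrix(object@weights)
    if (!isTRUE(msg)) return(msg)
    if (length(object@modality) != 1L ||
        !object@modality %in% c("structural", "functional"))
      return("modality must be 'structural' or 'functional'")
    if (is.null(rownames(object@weights)))
      return("weights must carry region labels as dimnames")
    TRUE
  })

#' Intrahemispheric weighted network
#'
#' The 45 x 45 (one node per homotopic pair) weighted network of one
#' hemisphere, ordered by homotopic pair index so that row k of a subject's
#' left network corresponds to row k of the right network.
#'
#' @slot weights numeric matrix ordered by pair index; dimnames are the
#'   pair-level region abbreviations.
#' @slot subjectId character scalar.
#' @slot modality \code{"structural"} or \code{"functional"}.
#' @slot hemisphere \code{"L"} or \code{"R"}.
#' @slot sparsity numeric scalar in (0, 1], or \code{NA_real_} when the
#'   network has not been sparsity-thresholded.
#' @slot normalized logical; \code{TRUE} after joint max-weight normalization.
#' @slot flags list of diagnostic flags (e.g. \code{unreachableSparsity}).
#' @export
setClass("HemiNetwork",
  representation(weights = "matrix", subjectId = "character",
                 modality = "character", hemisphere = "character",
                 sparsity = "numeric", normalized = "logical",
                 flags = "list"),
  prototype(sparsity = NA_real_, normalized = FALSE, flags = list()),
  validity = function(object) {
    msg <- .checkWeightMatrix(object@weights)
    if (!isTRUE(msg)) return(msg)
    if (!object@hemisphere %in% c("L", "R"))
      return("hemisphere must be 'L' or 'R'")
    if (!object@modality %in% c("structural", "functional"))
      return("modality must be 'structural' or 'functional'")
    s <- object@sparsity
    if (length(s) != 1L || (!is.na(s) && (s <= 0 || s > 1)))
      return("sparsity must be NA or in (0, 1]")
    TRUE
  })

#' Paired network-based-statistic result
#'
#' Holds the homotopic edge-wise paired t map, the suprathreshold connected
#' components for each tail, the permutation null distribution of maximal
#' component size, and the corrected p-value per component.
#'
#' @slot tMap numeric matrix of paired t statistics per homotopic edge.
#' @slot tThreshold component-forming threshold (applied as |t| > threshold
#'   within each tail).
#' @slot components list with elements \code{positive} (left > right) and
#'   \code{negative} (right > left); each a list of components with fields
#'   \code{edges} (2-column matrix of node indices), \code{nodes},
#'   \code{size} (edge count) and \code{p} (corrected).
#' @slot nullMaxSizes integer matrix (nPerm x 2, columns positive/negative)
#'   of maximal component sizes under permutation.
#' @slot nPerm number of permutations (2^n in exhaustive mode).
#' @slot exhaustive logical; TRUE when all 2^n sign flips were enumerated.
#' @slot seed RNG seed used for the permutation stream.
#' @export
setClass("NBSResult",
  representation(tMap = "matrix", tThreshold = "numeric",
                 components = "list", nullMaxSizes = "matrix",
                 nPerm = "integer", exhaustive = "logical",
                 seed = "integer"),
  validity = function(object) {
    if (object@tThreshold <= 0) return("tThreshold must be positive")
    if (nrow(object@nullMaxSizes) != object@nPerm)
      return("nullMaxSizes must have one row per permutation")
    ps <- unlist(lapply(unlist(object@components, recursive = FALSE),
                        `[[`, "p"))
    if (length(ps) && any(ps <= 0 | ps > 1))
      return("component p-values must lie in (0, 1]")
    TRUE
  })

#' @rdname weights
#' @export
setMethod("weights", "ConnectomeMatrix", function(object, ...) object@weights)

#' @rdname weights
#' @export
setMethod("weights", "HemiNetwork", function(object, ...) object@weights)

#' @rdname subjectId
#' @export
setMethod("subjectId", "ConnectomeMatrix", function(object) object@subjectId)

#' @rdname subjectId
#' @export
setMethod("subjectId", "HemiNetwork", function(object) object@subjectId)

#' @rdname modality
#' @export
setMethod("modality", "ConnectomeMatrix", function(object) object@modality)

#' @rdname modality
#' @export
setMethod("modality", "HemiNetwork", function(object) object@modality)

#' @rdname hemisphere
#' @export
setMethod("hemisphere", "HemiNetwork", function(object) object@hemisphere)

#' @rdname sparsity
#' @export
setMethod("sparsity", "HemiNetwork", function(object) object@sparsity)

setMethod("show", "ConnectomeMatrix", function(object) {
  w <- object@weights
  cat(sprintf("ConnectomeMatrix: subject '%s', %s, %d regions, %d edges\n",
              object@subjectId, object@modality, nrow(w),
              sum(w[upper.tri(w)] > 0)))
})

setMethod("show", "HemiNetwork", function(object) {
  w <- object@weights
  cat(sprintf(
    "HemiNetwork: subject '%s', %s, hemisphere %s, %d nodes, %d edges%s%s\n",
    object@subjectId, object@modality, object@hemisphere, nrow(w),
    sum(w[upper.tri(w)] > 0),
    if (is.na(object@sparsity)) " (unthresholded)"
    else sprintf(" (sparsity %.2f)", object@sparsity),
    if (object@normalized) ", normalized" else ""))
})

setMethod("show", "NBSResult", function(object) {
  np <- length(object@components$positive)
  nn <- length(object@components$negative)
  cat(sprintf(
    "NBSResult: |t| > %.2f, %d permutations%s\n  left>right components: %d; right>left components: %d\n",
    object@tThreshold, object@nPerm,
    if (object@exhaustive) " (exhaustive)" else "", np, nn))
  comps <- c(object@components$positive, object@components$negative)
  if (length(comps)) {
    sz <- vapply(comps, `[[`, 0, "size")
    p <- vapply(comps, `[[`, 0, "p")
    cat(sprintf("  largest component: %d edges (p = %.4g)\n",
                max(sz), p[which.max(sz)]))
  } else cat("  no suprathreshold connectivity\n")
})

# internal constructors
.ConnectomeMatrix <- function(weights, subjectId, modality) {
  new("ConnectomeMatrix", weights = weights, subjectId = subjectId,
      modality = modality)
}

.HemiNetwork <- function(weights, subjectId, modality, hemisphere,
                         sparsity = NA_real_, normalized = FALSE,
                         flags = list()) {
  new("HemiNetwork", weights = weights, subjectId = subjectId,
      modality = modality, hemisphere = hemisphere, sparsity = sparsity,
      normalized = normalized, flags = flags)
}
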