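#' Functional connectivity from ROI time series
#'
#' Pairwise Pearson correlation between all region pairs, Fisher r-to-z
#' transformed (atanh), with negative connections set to zero.  Correlations
#' are clipped to |r| <= 0.999999 before the transform so that degenerate
#' perfect correlations remain finite.
#'
#' @param timeseries numeric matrix, time points x regions (>= 3 rows), with
#'   region labels as column names.
#' @param subjectId subject label.
#' @return A \linkS4class{ConnectomeMatrix} (modality \code{"functional"}).
#' @examples
#' ts <- simulateRoiTimeseries(nTimepoints = 100, seed = 1)
#' functionalConnectivity(ts)
#' @export
functionalConnectivity <- function(timeseries, subjectId = "subject") {
  .stopifnot2(is.matrix(timeseries) && nrow(timeseries) >= 3,
              "timeseries must be a matrix with >= 3 time points")
  if (any(!is.finite(timeseries)))
    stop("timeseries contains non-finite values")
  v <- apply(timeseries, 2, stats::var)
  if (any(v == 0)) {
    lab <- colnames(timeseries)[which(v == 0)[1]]
    stop("zero-variance time series for region ",
         if (is.null(lab)) which(v == 0)[1] else lab)
  }
  r <- stats::cor(timeseries)
  r <- pmin(pmax(r, -0.999999), 0.999999)
  z <- atanh(r)
  z[z < 0] <- 0
  diag(z) <- 0
  z <- (z + t(z)) / 2  # symmetrize away floating asymmetry from cor()
  if (is.null(colnames(timeseries)))
    dimnames(z) <- list(seq_len(ncol(timeseries)), seq_len(ncol(timeseries)))
  .ConnectomeMatrix(z, subjectId, "functional")
}

#' Structural streamline-density connectome
#'
#' Edge weight between regions i and j is the streamline count divided by the
#' sum of the two region volumes, correcting connection counts for region
#' size.
#'
#' @param streamlineCounts symmetric nonnegative integer matrix of streamline
#'   counts, with region labels as dimnames.
#' @param roiVolumes strictly positive numeric vector of region volumes, one
#'   per region.
#' @param subjectId subject label.
#' @return A \linkS4class{ConnectomeMatrix} (modality \code{"structural"}).
#' @export
structuralDensity <- function(streamlineCounts, roiVolumes,
                              subjectId = "subject") {
  .stopifnot2(is.matrix(streamlineCounts), "streamlineCounts must be a matrix")
  .stopifnot2(length(roiVolumes) == nrow(streamlineCounts),
              "one volume per region required")
  if (any(roiVolumes <= 0))
    stop("region volumes must be strictly positive (region ",
         which(roiVolumes <= 0)[1], ")")
  if (any(streamlineCounts < 0) || any(streamlineCounts != t(streamlineCounts)))
    stop("streamlineCounts must be symmetric and nonnegative")
  denom <- outer(roiVolumes, roiVolumes, `+`)
  w <- streamlineCounts / denom
  diag(w) <- 0
  if (is.null(dimnames(w)))
    dimnames(w) <- list(seq_along(roiVolumes), seq_along(roiVolumes))
  .ConnectomeMatrix(w, subjectId, "structural")
}

#' Split a whole-brain connectome into hemispheric networks
#'
#' Discards all interhemispheric connections and returns the left and right
#' intrahemispheric blocks, with rows and columns sorted by homotopic pair
#' index so that node k of the left network is homotopic to node k of the
#' right network.
#'
#' @param cm a \linkS4class{ConnectomeMatrix}.
#' @param nodeTable node table whose labels match \code{rownames(weights(cm))}.
#' @return Named list with elements \code{L} and \code{R}, each a
#'   \linkS4class{HemiNetwork}.
#' @examples
#' cm <- simulateStructuralConnectome(seed = 1)
#' hn <- splitHemispheres(cm)
#' hn$L
#' @export
splitHemispheres <- function(cm, nodeTable = aal90NodeTable()) {
  validateNodeTable(nodeTable)
  w <- weights(cm)
  if (!identical(rownames(w), nodeTable$label))
    stop("connectome row labels do not match the node table")
  abbr <- .pairAbbr(nodeTable)
  out <- lapply(c(L = "L", R = "R"), function(h) {
    rows <- which(nodeTable$hemisphere == h)
    rows <- rows[order(nodeTable$pairIndex[rows])]
    b <- w[rows, rows, drop = FALSE]
    dimnames(b) <- list(abbr, abbr)
    .HemiNetwork(b, subjectId(cm), modality(cm), h)
  })
  out
}

#' Sparsity-threshold a hemispheric network
#'
#' Keeps exactly \code{round(s * N(N-1)/2)} largest-weight edges (rounding
#' half away from zero) with their original supra-threshold weights; all
#' other entries are set to zero.  Ties at the cutoff are broken
#' deterministically: descending weight, then ascending (i, j) lexicographic
#' order.  If fewer nonzero edges exist than requested, all nonzero edges are
#' kept and the flag \code{unreachableSparsity} is set.
#'
#' @param hn a \linkS4class{HemiNetwork} (unthresholded).
#' @param s target sparsity in (0, 1].
#' @return The thresholded \linkS4class{HemiNetwork}.
#' @export
thresholdSparsity <- function(hn, s) {
  .stopifnot2(s > 0 && s <= 1, "sparsity must be in (0, 1]")
  w <- weights(hn)
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  k <- .roundHalfUp(s * n * (n - 1) / 2)
  wv <- w[upper.tri(w)]
  ord <- order(-wv, ut[, 1L], ut[, 2L])
  nz <- sum(wv > 0)
  flags <- hn@flags
  if (k > nz) {
    flags$unreachableSparsity <- TRUE
    k <- nz
  }
  keep <- ord[seq_len(k)]
  out <- matrix(0, n, n, dimnames = dimnames(w))
  out[ut[keep, , drop = FALSE]] <- wv[keep]
  out <- out + t(out)
  .HemiNetwork(out, subjectId(hn), modality(hn), hemisphere(hn),
               sparsity = s, normalized = hn@normalized, flags = flags)
}

#' Threshold a hemispheric network over a sparsity grid
#'
#' Applies \code{\link{thresholdSparsity}} at every level of the inclusive
#' grid \code{seq(sMin, sMax, step)}.  The deterministic tie-break makes the
#' edge sets nested across levels.  The defaults give the 26 levels
#' 0.10, 0.11, ..., 0.35.
#'
#' @param hn a \linkS4class{HemiNetwork}.
#' @param sMin,sMax,step grid bounds and spacing; \code{sMin < sMax},
#'   \code{step > 0}.  A step larger than the range yields the single level
#'   \code{sMin}.
#' @return Named list of \linkS4class{HemiNetwork}, names are the sparsity
#'   levels.
#' @export
sparsitySeries <- function(hn, sMin = 0.10, sMax = 0.35, step = 0.01) {
  .stopifnot2(sMin < sMax, "need sMin < sMax")
  .stopifnot2(step > 0, "step must be positive")
  levels <- seq(sMin, sMax, by = step)
  levels <- round(levels, 10)
  if (!length(levels)) stop("empty sparsity grid")
  out <- lapply(levels, function(s) thresholdSparsity(hn, s))
  names(out) <- formatC(levels, format = "g")
  out
}
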