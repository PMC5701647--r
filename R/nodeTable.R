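.aal90 <- data.frame(
  abbr = c("AMYG", "ANG", "ACG", "CAL", "CAU", "CUN", "FFG", "REC", "HES",
           "HIP", "IFGoperc", "IFGtriang", "IOG", "IPL", "ITG", "INS",
           "LING", "MCG", "MFG", "MOG", "MTG", "OLF", "ORBsup", "ORBinf",
           "ORBmed", "ORBmid", "PAL", "PCL", "PHG", "PoCG", "PCG", "PreCG",
           "PCUN", "PUT", "ROL", "SFGdor", "SFGmed", "SOG", "SPG", "STG",
           "SMA", "SMG", "TPOmid", "TPOsup", "THA"),
  regionClass = c("Paralimbic", "Association", "Paralimbic", "Primary",
                  "Subcortical", "Association", "Association", "Paralimbic",
                  "Primary", "Subcortical", "Association", "Association",
                  "Association", "Association", "Association", "Paralimbic",
                  "Association", "Paralimbic", "Association", "Association",
                  "Association", "Paralimbic", "Paralimbic", "Paralimbic",
                  "Paralimbic", "Paralimbic", "Subcortical", "Association",
                  "Paralimbic", "Primary", "Paralimbic", "Primary",
                  "Association", "Subcortical", "Association", "Association",
                  "Association", "Association", "Association", "Association",
                  "Association", "Association", "Paralimbic", "Paralimbic",
                  "Subcortical"),
  stringsAsFactors = FALSE)

#' Default AAL-90 node table
#'
#' Returns the node table for the 90-region AAL parcellation: 45 homotopic
#' region pairs, one node per hemisphere, with the standard region
#' abbreviations and a coarse cytoarchitectonic class (Primary, Association,
#' Paralimbic, Subcortical).  All whole-brain matrices in the package share
#' this row/column order: the 45 left-hemisphere nodes first (in pair-index
#' order), then the 45 right-hemisphere nodes.
#'
#' @return A data.frame with 90 rows and columns \code{label} (unique node
#'   label, e.g. \code{"AMYG.L"}), \code{abbr} (pair-level abbreviation),
#'   \code{hemisphere} (\code{"L"}/\code{"R"}), \code{pairIndex} (1--45,
#'   homotopic pair identity) and \code{regionClass}.
#' @examples
#' nt <- aal90NodeTable()
#' table(nt$hemisphere)
#' @export
aal90NodeTable <- function() {
  n <- nrow(.aal90)
  out <- data.frame(
    label = c(paste0(.aal90$abbr, ".L"), paste0(.aal90$abbr, ".R")),
    abbr = rep(.aal90$abbr, 2L),
    hemisphere = rep(c("L", "R"), each = n),
    pairIndex = rep(seq_len(n), 2L),
    regionClass = rep(.aal90$regionClass, 2L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Validate a node table
#'
#' Checks the structural invariants required by the hemispheric analysis:
#' equal hemisphere sizes, pair indices forming a bijection between
#' hemispheres, and abbreviations unique within hemisphere.
#'
#' @param nodeTable data.frame as returned by \code{\link{aal90NodeTable}}.
#' @return The node table, invisibly; stops with an informative error when an
#'   invariant is violated.
#' @export
validateNodeTable <- function(nodeTable) {
  need <- c("label", "abbr", "hemisphere", "pairIndex")
  if (!all(need %in% names(nodeTable)))
    stop("node table must have columns: ", paste(need, collapse = ", "))
  if (!all(nodeTable$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  nl <- sum(nodeTable$hemisphere == "L")
  nr <- sum(nodeTable$hemisphere == "R")
  if (nl != nr)
    stop(sprintf("hemispheres must be the same size (L = %d, R = %d)", nl, nr))
  pl <- sort(nodeTable$pairIndex[nodeTable$hemisphere == "L"])
  pr <- sort(nodeTable$pairIndex[nodeTable$hemisphere == "R"])
  if (anyDuplicated(pl) || anyDuplicated(pr) || !identical(pl, pr) ||
      !identical(pl, seq_len(nl)))
    stop("pairIndex must form a bijection between hemispheres (1..n per side)")
  for (h in c("L", "R")) {
    a <- nodeTable$abbr[nodeTable$hemisphere == h]
    if (anyDuplicated(a))
      stop("duplicated abbreviation within hemisphere ", h, ": ",
           a[duplicated(a)][1])
  }
  invisible(nodeTable)
}

# pair-level abbreviations in pairIndex order
.pairAbbr <- function(nodeTable) {
  l <- nodeTable[nodeTable$hemisphere == "L", ]
  l$abbr[order(l$pairIndex)]
}
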