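# On-disk formats: labeled TSV matrices and tables with '#'-prefixed comment
# headers carrying tool version, seed and parameters.

.headerLines <- function(meta) {
  if (is.null(meta) || !length(meta)) return(character(0))
  paste0("# ", names(meta), ": ", vapply(meta, function(v)
    paste(format(v, digits = 15), collapse = " "), character(1)))
}

#' Write a labeled matrix as TSV
#'
#' Full-precision decimal rendering (17 significant digits) so that a
#' write-read round trip reproduces values and label order exactly.  Comment
#' lines (\code{# key: value}) record provenance.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output file.
#' @param meta named list written as comment header lines.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTSV <- function(mat, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.headerLines(meta), con)
  writeLines(paste(c("region", colnames(mat)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a labeled TSV matrix
#'
#' Inverse of \code{\link{writeMatrixTSV}}.  Validates squareness, symmetry
#' (tolerance 1e-8) and, when a node table or modality is supplied, label
#' order and the nonnegativity rule for functional weights.
#'
#' @param path input file.
#' @param nodeTable optional node table; labels must match in order.
#' @param modality optional; \code{"functional"} additionally rejects
#'   negative weights (only positive connections are retained by
#'   construction).
#' @return Numeric matrix with dimnames.
#' @export
readMatrixTSV <- function(path, nodeTable = NULL, modality = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  labs <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labs
  if (nrow(m) != ncol(m))
    stop(sprintf("matrix in '%s' is not square (%d x %d)", path,
                 nrow(m), ncol(m)))
  if (!identical(labs, colnames(m)))
    stop("row labels do not match column labels in ", path)
  asym <- abs(m - t(m)) > 1e-8
  if (any(asym)) {
    bad <- sort(which(asym, arr.ind = TRUE)[1, ])
    stop(sprintf("matrix in '%s' asymmetric at (%s, %s)", path,
                 labs[bad[1]], labs[bad[2]]))
  }
  if (!is.null(modality) && modality == "functional" && any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "negative functional weight at (%s, %s): only positive connections are retained",
      labs[bad[1]], labs[bad[2]]))
  }
  if (!is.null(nodeTable) && !identical(labs, nodeTable$label))
    stop("matrix labels do not match the node table in ", path)
  m
}

.writeTableTSV <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.headerLines(meta), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTableTSV <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a node table as TSV
#' @param nodeTable node table data.frame.
#' @param path output file.
#' @param meta comment-header metadata.
#' @return \code{path}, invisibly.
#' @export
writeNodeTable <- function(nodeTable, path, meta = NULL)
  .writeTableTSV(nodeTable, path, meta)

#' Read a node table from TSV
#' @param path input file.
#' @return Validated node table data.frame.
#' @export
readNodeTable <- function(path) validateNodeTable(.readTableTSV(path))

#' Default pipeline configuration
#'
#' Collects every tunable of the end-to-end run: cohort generation, sparsity
#' grid (0.10--0.35 by 0.01, 26 levels), number of rewired nulls, NBS
#' threshold and permutations, FDR level, and modality toggles.  The
#' analysis defaults (nNull, nPerm) are sized for a desk-scale synthetic
#' cohort; raise them (100 nulls, 5000 permutations are the conventional
#' full-scale choices) for production runs.
#'
#' @param nSubjects cohort size.
#' @param cohort cohort generator configuration (\code{\link{cohortConfig}}).
#' @param sparsity list with \code{min}, \code{max}, \code{step}.
#' @param nNull rewired nulls per network (and per sparsity level for the
#'   functional arm).
#' @param nbs list with \code{tThreshold}, \code{nPerm}.
#' @param fdrQ FDR level for the hemisphere-effect scan.
#' @param alpha uncorrected threshold for the association scan.
#' @param modalities character subset of \code{c("structural", "functional")}.
#' @param seed master seed.
#' @return Nested named list.
#' @export
pipelineConfig <- function(nSubjects = 20L, cohort = cohortConfig(),
                           sparsity = list(min = 0.10, max = 0.35,
                                           step = 0.01),
                           nNull = 5L,
                           nbs = list(tThreshold = 3.0, nPerm = 500L),
                           fdrQ = 0.05, alpha = 0.05,
                           modalities = c("structural", "functional"),
                           seed = 1L) {
  .stopifnot2(all(modalities %in% c("structural", "functional")),
              "unknown modality")
  list(nSubjects = as.integer(nSubjects), cohort = cohort,
       sparsity = sparsity, nNull = as.integer(nNull), nbs = nbs,
       fdrQ = fdrQ, alpha = alpha, modalities = modalities,
       seed = as.integer(seed))
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the defaults of
#' \code{\link{pipelineConfig}}; nested keys merge recursively.
#'
#' @param path YAML file.
#' @return Pipeline configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  merge2 <- function(base, over) {
    for (k in names(over)) {
      if (is.list(base[[k]]) && is.list(over[[k]]))
        base[[k]] <- merge2(base[[k]], over[[k]])
      else base[[k]] <- over[[k]]
    }
    base
  }
  cfg <- merge2(pipelineConfig(), user)
  cfg$nSubjects <- as.integer(cfg$nSubjects)
  cfg$nNull <- as.integer(cfg$nNull)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
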