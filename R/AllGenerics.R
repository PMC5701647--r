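#' @import methods
#' @importFrom stats weights
NULL

#' Extract the weighted adjacency matrix
#'
#' @param object A \linkS4class{ConnectomeMatrix} or \linkS4class{HemiNetwork}.
#' @param ... Ignored.
#' @return Numeric matrix of edge weights (symmetric, zero diagonal).
#' @export
setGeneric("weights")

#' Subject identifier accessor
#' @param object A connectome object.
#' @return Character scalar.
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' Modality accessor
#' @param object A connectome object.
#' @return Either \code{"structural"} or \code{"functional"}.
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))

#' Hemisphere accessor
#' @param object A \linkS4class{HemiNetwork}.
#' @return Either \code{"L"} or \code{"R"}.
#' @export
setGeneric("hemisphere", function(object) standardGeneric("hemisphere"))

#' Sparsity accessor
#' @param object A \linkS4class{HemiNetwork}.
#' @return Sparsity level in (0, 1], or \code{NA_real_} if unthresholded.
#' @export
setGeneric("sparsity", function(object) standardGeneric("sparsity"))
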