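#' Hemispheric asymmetry score
#'
#' \eqn{AS(X) = 100 [X(R) - X(L)] / [X(R) + X(L)]}, bounded in [-100, +100]
#' for nonnegative metric values.  For every metric except L_w a positive
#' score indicates rightward asymmetry; because longer path length means less
#' efficient global integration, a positive AS(L_w) indicates a leftward
#' advantage (the stored number always follows the formula unmodified — the
#' interpretation flip is metadata only).
#'
#' @param xR,xL metric values of the right and left hemisphere (>= 0, not
#'   both 0).
#' @return The asymmetry score; \code{NA} with a warning when both values are
#'   zero.
#' @examples
#' asymmetryScore(3, 1)  # +50
#' @export
asymmetryScore <- function(xR, xL) {
  out <- 100 * (xR - xL) / (xR + xL)
  und <- (xR + xL) == 0
  if (any(und)) {
    warning("asymmetry undefined where both hemispheres are zero")
    out[und] <- NA_real_
  }
  out
}

#' Asymmetry profile of one subject
#'
#' One asymmetry score per global metric (C_w, L_w, sigma, E_global,
#' E_local) and one per region (E_nodal), from the left- and
#' right-hemisphere metric lists of one subject and modality.
#'
#' @param mL,mR metric lists from \code{\link{hemiMetrics}} or
#'   \code{\link{integratedMetrics}} for the left and right hemisphere.
#' @param subjectId,modality labels copied into the output.
#' @return data.frame with columns \code{subject_id}, \code{modality},
#'   \code{level} (\code{"global"}/\code{"regional"}), \code{metric},
#'   \code{X_L}, \code{X_R}, \code{AS}.
#' @export
subjectAsymmetryProfile <- function(mL, mR, subjectId = "subject",
                                    modality = "structural") {
  glb <- intersect(c("Cw", "Lw", "sigma", "Eglobal", "Elocal"),
                   intersect(names(mL), names(mR)))
  if (!identical(names(mL$Enodal), names(mR$Enodal)))
    stop("regional metric vectors are not homotopically aligned")
  gl <- data.frame(
    subject_id = subjectId, modality = modality, level = "global",
    metric = glb,
    X_L = vapply(glb, function(m) mL[[m]], numeric(1)),
    X_R = vapply(glb, function(m) mR[[m]], numeric(1)),
    stringsAsFactors = FALSE)
  rg <- data.frame(
    subject_id = subjectId, modality = modality, level = "regional",
    metric = paste0("Enodal_", names(mL$Enodal)),
    X_L = unname(mL$Enodal), X_R = unname(mR$Enodal),
    stringsAsFactors = FALSE)
  out <- rbind(gl, rg)
  out$AS <- suppressWarnings(asymmetryScore(out$X_R, out$X_L))
  if (anyNA(out$AS))
    warning("asymmetry undefined (both hemispheres zero) for: ",
            paste(out$metric[is.na(out$AS)], collapse = ", "))
  rownames(out) <- NULL
  out
}
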