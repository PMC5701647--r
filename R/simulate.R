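#' Specification of injected hemispheric asymmetry
#'
#' Describes the ground-truth lateralization injected by the synthetic
#' generators: a global multiplicative scaling of one hemisphere's
#' intrahemispheric weights, per-node scalings, and per-edge scalings on a
#' designated homotopic edge subnetwork.  Effects are multiplicative
#' (\code{weight * (1 + delta)}) on the target hemisphere's block; edges
#' incident to two nodal targets receive both nodal factors.
#'
#' @param globalScaleDelta real; the target hemisphere's weights are
#'   multiplied by \code{1 + globalScaleDelta}.  Must satisfy
#'   \code{1 + globalScaleDelta > 0}.
#' @param nodalTargets \code{NULL} or data.frame with columns
#'   \code{pairIndex} (1--45) and \code{delta}.
#' @param edgeSubnetwork \code{NULL} or data.frame with columns \code{i},
#'   \code{j} (pair indices, \code{i < j}, each edge listed once) and
#'   \code{delta}.
#' @param direction \code{"leftward"} (effects applied to the left block,
#'   the default) or \code{"rightward"}.
#' @return A list of class \code{"AsymmetrySpec"}.
#' @examples
#' asymmetrySpec(globalScaleDelta = 0.1)
#' @export
asymmetrySpec <- function(globalScaleDelta = 0, nodalTargets = NULL,
                          edgeSubnetwork = NULL, direction = "leftward") {
  .stopifnot2(1 + globalScaleDelta > 0, "1 + globalScaleDelta must be > 0")
  direction <- match.arg(direction, c("leftward", "rightward"))
  if (!is.null(nodalTargets)) {
    .stopifnot2(all(c("pairIndex", "delta") %in% names(nodalTargets)),
                "nodalTargets needs columns pairIndex, delta")
    .stopifnot2(all(1 + nodalTargets$delta > 0), "1 + nodal delta must be > 0")
  }
  if (!is.null(edgeSubnetwork)) {
    .stopifnot2(all(c("i", "j", "delta") %in% names(edgeSubnetwork)),
                "edgeSubnetwork needs columns i, j, delta")
    .stopifnot2(all(edgeSubnetwork$i < edgeSubnetwork$j),
                "edgeSubnetwork edges must have i < j")
    key <- paste(edgeSubnetwork$i, edgeSubnetwork$j)
    .stopifnot2(!anyDuplicated(key), "edgeSubnetwork edges must be unique")
  }
  structure(list(globalScaleDelta = globalScaleDelta,
                 nodalTargets = nodalTargets,
                 edgeSubnetwork = edgeSubnetwork,
                 direction = direction),
            class = "AsymmetrySpec")
}

# multiplicative factor matrix (45 x 45, zero-diagonal cells meaningful only
# off-diagonal) encoding all spec effects on the target hemisphere block
.specFactorMatrix <- function(spec, n = 45L) {
  f <- matrix(1 + spec$globalScaleDelta, n, n)
  if (!is.null(spec$nodalTargets)) {
    for (r in seq_len(nrow(spec$nodalTargets))) {
      p <- spec$nodalTargets$pairIndex[r]
      f[p, ] <- f[p, ] * (1 + spec$nodalTargets$delta[r])
      f[, p] <- f[, p] * (1 + spec$nodalTargets$delta[r])
      f[p, p] <- 1  # diagonal unused
    }
  }
  if (!is.null(spec$edgeSubnetwork)) {
    for (r in seq_len(nrow(spec$edgeSubnetwork))) {
      i <- spec$edgeSubnetwork$i[r]; j <- spec$edgeSubnetwork$j[r]
      f[i, j] <- f[i, j] * (1 + spec$edgeSubnetwork$delta[r])
      f[j, i] <- f[i, j]
    }
  }
  f
}

#' Default structural generator parameters
#'
#' Edge density and log-normal weight parameters emulating sparse
#' streamline-density networks from deterministic tractography on a 45-node
#' hemisphere, plus the per-subject multiplicative noise level.
#'
#' @param densityIntra intrahemispheric edge density in (0, 1].
#' @param densityInter interhemispheric edge density in (0, 1].
#' @param weightMeanlog,weightSdlog log-normal weight parameters.
#' @param noiseSd standard deviation of the per-edge multiplicative
#'   log-normal subject noise (0 disables noise).
#' @return Named list of parameters.
#' @export
structuralParams <- function(densityIntra = 0.3, densityInter = 0.1,
                             weightMeanlog = log(0.05), weightSdlog = 0.8,
                             noiseSd = 0.1) {
  .stopifnot2(densityIntra > 0 && densityIntra <= 1,
              "densityIntra must be in (0, 1]")
  .stopifnot2(densityInter > 0 && densityInter <= 1,
              "densityInter must be in (0, 1]")
  .stopifnot2(noiseSd >= 0, "noiseSd must be >= 0")
  list(densityIntra = densityIntra, densityInter = densityInter,
       weightMeanlog = weightMeanlog, weightSdlog = weightSdlog,
       noiseSd = noiseSd)
}

#' Simulate a structural streamline-density connectome
#'
#' Generates one subject's 90 x 90 symmetric structural network.  A single
#' sparse log-normal-weight template is drawn for one hemisphere and mirrored
#' to the other, so that with a null asymmetry spec and zero noise the left
#' intrahemispheric block equals the mirrored right block exactly; subject
#' noise is independent multiplicative log-normal per hemisphere, and the
#' asymmetry spec is applied multiplicatively to the target hemisphere's
#' block.  Interhemispheric edges are generated for realism but carry no
#' asymmetry signal (the analysis discards them).
#'
#' @param nodeTable node table (see \code{\link{aal90NodeTable}}).
#' @param baseParams list from \code{\link{structuralParams}}.
#' @param spec an \code{\link{asymmetrySpec}}.
#' @param seed integer RNG seed (subject noise and interhemispheric edges).
#' @param subjectId subject label for the returned object.
#' @param templateSeed optional separate seed for the shared anatomical
#'   template.  Subjects of one cohort are given the same
#'   \code{templateSeed}, so they share edge placement and baseline weights
#'   (as human subjects share gross anatomy) and differ only in noise and
#'   injected effects; the default (\code{NULL}) uses \code{seed}, giving a
#'   self-contained single-subject draw.
#' @return A \linkS4class{ConnectomeMatrix} (modality \code{"structural"}).
#' @examples
#' cm <- simulateStructuralConnectome(seed = 1)
#' cm
#' @export
simulateStructuralConnectome <- function(nodeTable = aal90NodeTable(),
                                         baseParams = structuralParams(),
                                         spec = asymmetrySpec(),
                                         seed = 1L,
                                         subjectId = "sim",
                                         templateSeed = NULL) {
  validateNodeTable(nodeTable)
  n <- sum(nodeTable$hemisphere == "L")
  set.seed(if (is.null(templateSeed)) seed else templateSeed)
  ut <- upper.tri(matrix(0, n, n))
  m <- sum(ut)
  present <- stats::runif(m) < baseParams$densityIntra
  wvec <- ifelse(present,
                 stats::rlnorm(m, baseParams$weightMeanlog,
                               baseParams$weightSdlog), 0)
  tmpl <- matrix(0, n, n)
  tmpl[ut] <- wvec
  tmpl <- tmpl + t(tmpl)
  # edges named in the spec's subnetwork must exist in the template
  if (!is.null(spec$edgeSubnetwork)) {
    for (r in seq_len(nrow(spec$edgeSubnetwork))) {
      i <- spec$edgeSubnetwork$i[r]; j <- spec$edgeSubnetwork$j[r]
      if (tmpl[i, j] == 0) {
        tmpl[i, j] <- stats::rlnorm(1, baseParams$weightMeanlog,
                                    baseParams$weightSdlog)
        tmpl[j, i] <- tmpl[i, j]
      }
    }
  }
  set.seed(seed)  # subject-specific stream: noise + interhemispheric edges
  noise <- function() {
    if (baseParams$noiseSd == 0) return(matrix(1, n, n))
    e <- matrix(0, n, n)
    e[ut] <- exp(stats::rnorm(m, 0, baseParams$noiseSd))
    e <- e + t(e); diag(e) <- 1
    e
  }
  left <- tmpl * noise()
  right <- tmpl * noise()
  f <- .specFactorMatrix(spec, n)
  diag(f) <- 1
  if (spec$direction == "leftward") left <- left * f else right <- right * f
  inter <- matrix(stats::runif(n * n) < baseParams$densityInter, n, n) *
    matrix(stats::rlnorm(n * n, baseParams$weightMeanlog,
                         baseParams$weightSdlog), n, n)
  w <- matrix(0, 2L * n, 2L * n)
  idxL <- order(nodeTable$pairIndex[nodeTable$hemisphere == "L"])
  # rows of nodeTable for hemisphere h, sorted by pairIndex
  rowL <- which(nodeTable$hemisphere == "L")[idxL]
  rowR <- which(nodeTable$hemisphere == "R")[
    order(nodeTable$pairIndex[nodeTable$hemisphere == "R"])]
  w[rowL, rowL] <- left
  w[rowR, rowR] <- right
  w[rowL, rowR] <- inter
  w[rowR, rowL] <- t(inter)
  diag(w) <- 0
  dimnames(w) <- list(nodeTable$label, nodeTable$label)
  .ConnectomeMatrix(w, subjectId, "structural")
}

#' Default functional covariance specification
#'
#' Block-modular population correlation for the simulated ROI time series:
#' contiguous modules of \code{moduleSize} regions within each hemisphere
#' correlate at \code{rhoIn}, other within-hemisphere pairs at \code{rhoOut},
#' interhemispheric pairs at \code{rhoCross} with homotopic pairs boosted to
#' \code{rhoHomotopic}.  The structure is mirrored across hemispheres.
#'
#' @param moduleSize regions per module (must divide 45 evenly or the last
#'   module is shorter).
#' @param rhoIn,rhoOut within/between-module correlation, \code{rhoIn > rhoOut >= 0}.
#' @param rhoCross,rhoHomotopic interhemispheric correlations.
#' @param repair logical; repair a non-positive-definite matrix by nearest-PD
#'   adjustment (with a warning) instead of erroring.
#' @return Named list.
#' @export
functionalCovSpec <- function(moduleSize = 5L, rhoIn = 0.5, rhoOut = 0.1,
                              rhoCross = 0.1, rhoHomotopic = 0.3,
                              repair = TRUE) {
  .stopifnot2(rhoIn >= rhoOut && rhoOut >= 0,
              "need rhoIn >= rhoOut >= 0")
  list(moduleSize = as.integer(moduleSize), rhoIn = rhoIn, rhoOut = rhoOut,
       rhoCross = rhoCross, rhoHomotopic = rhoHomotopic, repair = repair)
}

# population covariance in canonical (L then R, pairIndex) order
.functionalSigma <- function(covSpec, spec, n = 45L) {
  mod <- ceiling(seq_len(n) / covSpec$moduleSize)
  s <- matrix(covSpec$rhoOut, n, n)
  same <- outer(mod, mod, `==`)
  s[same] <- covSpec$rhoIn
  diag(s) <- 1
  cross <- matrix(covSpec$rhoCross, n, n)
  diag(cross) <- covSpec$rhoHomotopic
  sigma <- rbind(cbind(s, cross), cbind(t(cross), s))
  f <- .specFactorMatrix(spec, n)
  diag(f) <- 1
  tgt <- if (spec$direction == "leftward") seq_len(n) else n + seq_len(n)
  block <- sigma[tgt, tgt] * f
  diag(block) <- 1
  block <- pmin(block, 0.999)
  sigma[tgt, tgt] <- block
  sigma
}

#' Simulate ROI time series with modular covariance
#'
#' Draws \code{nTimepoints} x 90 zero-mean multivariate normal samples whose
#' population correlation is block-modular and mirrored across hemispheres
#' (see \code{\link{functionalCovSpec}}); the asymmetry spec scales the
#' target hemisphere's off-diagonal covariance entries to induce functional
#' lateralization.  Non-positive-definite covariances (possible after strong
#' injected effects) are repaired by nearest-PD adjustment with a warning, or
#' raise an error when \code{covSpec$repair} is \code{FALSE}.
#'
#' @param nodeTable node table.
#' @param covSpec list from \code{\link{functionalCovSpec}}.
#' @param nTimepoints number of time points (>= 50).
#' @param spec an \code{\link{asymmetrySpec}}.
#' @param seed integer RNG seed.
#' @return Numeric matrix (\code{nTimepoints} x 90) with region labels as
#'   column names, in node-table order.
#' @export
simulateRoiTimeseries <- function(nodeTable = aal90NodeTable(),
                                  covSpec = functionalCovSpec(),
                                  nTimepoints = 200L,
                                  spec = asymmetrySpec(),
                                  seed = 1L) {
  validateNodeTable(nodeTable)
  .stopifnot2(nTimepoints >= 50, "nTimepoints must be >= 50")
  n <- sum(nodeTable$hemisphere == "L")
  sigma <- .functionalSigma(covSpec, spec, n)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    if (!covSpec$repair)
      stop("population covariance is not positive definite (repair is off)")
    warning("population covariance repaired by nearest-PD adjustment")
    sigma <- as.matrix(Matrix::nearPD(sigma, corr = TRUE)$mat)
  }
  set.seed(seed)
  x <- MASS::mvrnorm(nTimepoints, mu = rep(0, 2L * n), Sigma = sigma)
  # canonical order -> node-table order
  rowL <- which(nodeTable$hemisphere == "L")[
    order(nodeTable$pairIndex[nodeTable$hemisphere == "L"])]
  rowR <- which(nodeTable$hemisphere == "R")[
    order(nodeTable$pairIndex[nodeTable$hemisphere == "R"])]
  out <- matrix(0, nTimepoints, 2L * n)
  out[, rowL] <- x[, seq_len(n)]
  out[, rowR] <- x[, n + seq_len(n)]
  colnames(out) <- nodeTable$label
  out
}

#' Behavioral score means and SDs
#'
#' Default mean/SD per behavioral column, emulating a neuropsychological
#' battery for a community-dwelling older-adult cohort (verbal memory, digit
#' span, processing speed, naming, visuospatial construction, trail-making,
#' and global cognition screens).
#'
#' @return data.frame with columns \code{score}, \code{mean}, \code{sd}.
#' @export
behaviorScoreParams <- function() {
  data.frame(
    score = c("RAVLT_ir", "RAVLT_dr", "DigitSpan_fwd", "DigitSpan_bwd",
              "SDMT_written", "SDMT_oral", "BostonNaming", "BlockDesign",
              "CTT1", "CTT2", "MMSE", "MoCA"),
    mean = c(47.18, 10.20, 10.54, 6.08, 31.95, 39.17, 22.13, 26.93,
             69.34, 136.10, 28.25, 25.75),
    sd = c(10.76, 3.04, 2.65, 2.21, 11.56, 12.89, 5.08, 9.15,
           26.86, 43.56, 1.81, 3.48),
    stringsAsFactors = FALSE)
}

#' Generate behavioral scores coupled to asymmetry
#'
#' Each coupled score is a linear function of the subject's (standardized)
#' asymmetry score plus independent Gaussian noise scaled so that the
#' population correlation with the asymmetry score equals \code{couplingR};
#' uncoupled scores are pure noise at the configured mean/SD.
#'
#' @param asScores numeric vector of per-subject asymmetry scores (>= 3).
#' @param couplingR target correlation, \code{|couplingR| < 1} (or exactly
#'   +/-1 for a noise-free linear score).
#' @param coupled character vector of score names receiving the coupling.
#' @param scoreParams data.frame as \code{\link{behaviorScoreParams}}.
#' @param seed integer RNG seed.
#' @return data.frame with one column per score.
#' @export
generateBehavior <- function(asScores, couplingR = 0, coupled = character(0),
                             scoreParams = behaviorScoreParams(), seed = 1L) {
  n <- length(asScores)
  .stopifnot2(n >= 3, "need at least 3 subjects")
  .stopifnot2(abs(couplingR) <= 1, "|couplingR| must be <= 1")
  .stopifnot2(all(coupled %in% scoreParams$score),
              "unknown coupled score name")
  set.seed(seed)
  sdAS <- stats::sd(asScores)
  z <- if (sdAS > 0) (asScores - mean(asScores)) / sdAS else rep(0, n)
  out <- lapply(seq_len(nrow(scoreParams)), function(k) {
    mu <- scoreParams$mean[k]; s <- scoreParams$sd[k]
    if (scoreParams$score[k] %in% coupled) {
      mu + s * (couplingR * z + sqrt(1 - couplingR^2) * stats::rnorm(n))
    } else {
      mu + s * stats::rnorm(n)
    }
  })
  names(out) <- scoreParams$score
  as.data.frame(out)
}

#' Default cohort configuration
#'
#' Nested configuration for \code{\link{simulateCohort}}: the structural and
#' functional generator parameters, the shared asymmetry spec (plus
#' between-subject SD of the global delta, which gives every subject a
#' well-defined true generating asymmetry score), behavioral coupling, and
#' covariate distributions emulating a community-dwelling older-adult cohort
#' (age 60--82, predominantly female, all right-handed).
#'
#' @param globalScaleDelta,globalDeltaSd mean and between-subject SD of the
#'   global hemisphere scaling delta.
#' @param direction \code{"leftward"} or \code{"rightward"}.
#' @param nodalTargets,edgeSubnetwork passed to \code{\link{asymmetrySpec}}.
#' @param couplingR,coupled behavioral coupling (see
#'   \code{\link{generateBehavior}}).
#' @param nTimepoints functional time-series length.
#' @param baseParams structural generator parameters.
#' @param covSpec functional covariance spec.
#' @return Nested named list.
#' @export
cohortConfig <- function(globalScaleDelta = 0, globalDeltaSd = 0.05,
                         direction = "leftward", nodalTargets = NULL,
                         edgeSubnetwork = NULL, couplingR = 0,
                         coupled = character(0), nTimepoints = 200L,
                         baseParams = structuralParams(),
                         covSpec = functionalCovSpec()) {
  list(spec = list(globalScaleDelta = globalScaleDelta,
                   globalDeltaSd = globalDeltaSd,
                   direction = direction,
                   nodalTargets = nodalTargets,
                   edgeSubnetwork = edgeSubnetwork),
       behavior = list(couplingR = couplingR, coupled = coupled),
       functional = list(covSpec = covSpec,
                         nTimepoints = as.integer(nTimepoints)),
       structural = list(baseParams = baseParams),
       covariates = list(ageMean = 70.08, ageSd = 5.30,
                         ageRange = c(60, 82), pFemale = 61 / 76,
                         educationMean = 6.00, educationSd = 3.98,
                         educationRange = c(0, 15)))
}

.rtrunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Simulate a full multimodal cohort
#'
#' Generates \code{nSubjects} paired structural connectomes and functional
#' ROI time series with known injected hemispheric asymmetry, covariates,
#' and behavioral scores coupled to each subject's true generating asymmetry
#' score.  Per-subject seeds are derived deterministically from the master
#' seed, so the bundle is reproducible independent of iteration order.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param config nested configuration from \code{\link{cohortConfig}}.
#' @param seed master integer seed.
#' @param nodeTable node table.
#' @return A list of class \code{"CohortBundle"} with elements
#'   \code{subjects} (each with \code{subjectId}, \code{structural}
#'   \linkS4class{ConnectomeMatrix}, \code{timeseries} matrix,
#'   \code{covariates}), \code{covariates} (data.frame), \code{behavior}
#'   (data.frame of the 12 battery scores), \code{truth} (all injected
#'   effects and per-subject generating asymmetry scores) and
#'   \code{nodeTable}.
#' @examples
#' cb <- simulateCohort(3, seed = 1)
#' names(cb$behavior)
#' @export
simulateCohort <- function(nSubjects, config = cohortConfig(), seed = 1L,
                           nodeTable = aal90NodeTable()) {
  .stopifnot2(nSubjects >= 2, "need at least 2 subjects")
  validateNodeTable(nodeTable)
  sp <- config$spec
  set.seed(.deriveSeed(seed, 0L, 3L))
  deltas <- sp$globalScaleDelta +
    stats::rnorm(nSubjects, 0, sp$globalDeltaSd)
  deltas <- pmax(deltas, -0.9)  # keep 1 + delta > 0
  cfac <- 1 + deltas
  trueAS <- if (sp$direction == "leftward")
    100 * (1 - cfac) / (1 + cfac) else 100 * (cfac - 1) / (cfac + 1)

  set.seed(.deriveSeed(seed, 0L, 5L))
  cv <- config$covariates
  age <- round(.rtrunc(nSubjects, cv$ageMean, cv$ageSd,
                       cv$ageRange[1], cv$ageRange[2]), 1)
  gender <- ifelse(stats::runif(nSubjects) < cv$pFemale, "F", "M")
  education <- round(.rtrunc(nSubjects, cv$educationMean, cv$educationSd,
                             cv$educationRange[1], cv$educationRange[2]))
  ids <- sprintf("S%03d", seq_len(nSubjects))

  tmplSeed <- .deriveSeed(seed, 0L, 7L)  # one anatomical template per cohort
  subjects <- lapply(seq_len(nSubjects), function(i) {
    speci <- asymmetrySpec(globalScaleDelta = deltas[i],
                           nodalTargets = sp$nodalTargets,
                           edgeSubnetwork = sp$edgeSubnetwork,
                           direction = sp$direction)
    list(subjectId = ids[i],
         structural = simulateStructuralConnectome(
           nodeTable, config$structural$baseParams, speci,
           seed = .deriveSeed(seed, i, 1L), subjectId = ids[i],
           templateSeed = tmplSeed),
         timeseries = simulateRoiTimeseries(
           nodeTable, config$functional$covSpec,
           config$functional$nTimepoints, speci,
           seed = .deriveSeed(seed, i, 2L)),
         covariates = list(age = age[i], gender = gender[i],
                           education = education[i], handedness = "R"))
  })
  behavior <- generateBehavior(trueAS, config$behavior$couplingR,
                               config$behavior$coupled,
                               seed = .deriveSeed(seed, 0L, 4L))
  covariates <- data.frame(subject_id = ids, age = age, gender = gender,
                           education = education, handedness = "R",
                           stringsAsFactors = FALSE)
  structure(list(
    subjects = subjects,
    covariates = covariates,
    behavior = cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE),
                     behavior),
    truth = list(spec = sp, deltas = deltas, trueAS = trueAS,
                 couplingR = config$behavior$couplingR,
                 coupled = config$behavior$coupled,
                 note = paste("all generator choices are package-defined;",
                              "no empirical generative model is implied")),
    nodeTable = nodeTable, seed = as.integer(seed)),
    class = "CohortBundle")
}

#' @export
print.CohortBundle <- function(x, ...) {
  cat(sprintf(
    "CohortBundle: %d subjects, %d behavioral scores, master seed %d\n",
    length(x$subjects), ncol(x$behavior) - 1L, x$seed))
  invisible(x)
}

#' Multiplicative delta for a target paired effect size
#'
#' For the structural generator's log-normal edge noise (SD \code{noiseSd}
#' on the log scale), returns the hemisphere scaling delta that yields a
#' paired Cohen's d of \code{effectSize} for the homotopic edge difference
#' \code{left - right}: with noise factors \code{e = exp(N(0, s^2))}, the
#' difference \code{T(e_L (1 + delta) - e_R)} has mean \code{T delta m1} and
#' variance \code{T^2 v ((1+delta)^2 + 1)} where \code{m1 = exp(s^2/2)} and
#' \code{v = exp(s^2)(exp(s^2) - 1)}; solving mean/SD = effectSize for delta
#' gives the returned root.
#'
#' @param effectSize target paired Cohen's d (> 0).
#' @param noiseSd structural generator noise SD (> 0).
#' @return The positive delta.
#' @export
pairedEffectDelta <- function(effectSize, noiseSd) {
  .stopifnot2(effectSize > 0 && noiseSd > 0,
              "effectSize and noiseSd must be positive")
  m1sq <- exp(noiseSd^2)
  v <- exp(noiseSd^2) * (exp(noiseSd^2) - 1)
  k <- effectSize^2
  # delta^2 (m1^2 - k v) - 2 k v delta - 2 k v = 0
  a <- m1sq - k * v; b <- -2 * k * v; cc <- -2 * k * v
  .stopifnot2(a > 0, "effect size unattainable at this noise level")
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}
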