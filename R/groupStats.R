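#' Hemisphere-effect ANCOVA with gender covariate
#'
#' Stacks one metric's left and right values as 2n observations and tests
#' the hemisphere factor by the full-versus-reduced linear model comparison
#' (full: intercept + hemisphere + gender; reduced: intercept + gender),
#' giving F with df (1, 2n - 3).
#'
#' @param left,right numeric vectors of the metric per subject and
#'   hemisphere.
#' @param gender per-subject factor (binary); repeated internally for the
#'   stacked observations.  A constant gender column is dropped with a
#'   warning (the denominator df then becomes 2n - 2).
#' @return List with \code{F}, \code{df} (numerator, denominator), \code{p},
#'   and \code{direction} (\code{"leftward"}, \code{"rightward"} or
#'   \code{"none"}); \code{F} is \code{NA} for a constant response.
#' @export
ancovaHemisphere <- function(left, right, gender) {
  n <- length(left)
  .stopifnot2(length(right) == n, "left/right length mismatch")
  .stopifnot2(length(gender) == n, "one gender per subject required")
  .stopifnot2(n >= 2, "need at least 2 subjects")
  y <- c(left, right)
  hemi <- factor(rep(c("L", "R"), each = n))
  g <- factor(rep(as.character(gender), 2))
  if (stats::var(y) == 0)
    return(list(F = NA_real_, df = c(NA_integer_, NA_integer_),
                p = NA_real_, direction = "none"))
  if (nlevels(g) < 2) {
    warning("gender is constant; covariate dropped")
    full <- stats::lm(y ~ hemi)
    red <- stats::lm(y ~ 1)
  } else {
    full <- stats::lm(y ~ hemi + g)
    red <- stats::lm(y ~ g)
  }
  rssF <- sum(stats::residuals(full)^2)
  rssR <- sum(stats::residuals(red)^2)
  dfden <- stats::df.residual(full)
  Fv <- if (rssF <= 0) Inf else (rssR - rssF) / (rssF / dfden)
  p <- stats::pf(Fv, 1, dfden, lower.tail = FALSE)
  dirn <- if (mean(left) > mean(right)) "leftward"
          else if (mean(left) < mean(right)) "rightward" else "none"
  list(F = Fv, df = c(1L, dfden), p = p, direction = dirn)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up procedure: with ordered p-values p(1) <= ... <= p(m), reject all
#' p(i) with \code{i <= max{i: p(i) <= i q / m}}.  Adjusted values follow the
#' standard monotone cumulative-minimum construction
#' (\code{p.adjust(method = "BH")}), so rejection is equivalent to
#' \code{adjusted <= q}.
#'
#' @param p vector of p-values in [0, 1].
#' @param q FDR level.
#' @return List with \code{adjusted} and logical \code{rejected} (empty for
#'   empty input).
#' @export
fdrBh <- function(p, q = 0.05) {
  if (!length(p)) return(list(adjusted = numeric(0), rejected = logical(0)))
  .stopifnot2(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation of the residuals of x and y after least-squares
#' regression on an intercept plus the covariates, with the two-sided p-value
#' from the t transform at df = n - nCovariates - 2.  Constant covariate
#' columns are dropped with a warning (e.g. handedness in an all-right-handed
#' cohort), so with only constant covariates the result reduces to the plain
#' Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates \code{NULL}, or a matrix/data.frame of covariates
#'   (factors/characters are expanded to indicator columns).
#' @return List with \code{r}, \code{df}, \code{p}; \code{r} is \code{NA}
#'   with a warning when a residual variance is zero.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  n <- length(x)
  .stopifnot2(length(y) == n, "x/y length mismatch")
  cm <- NULL
  if (!is.null(covariates)) {
    cdf <- as.data.frame(covariates, stringsAsFactors = FALSE)
    cm <- do.call(cbind, lapply(cdf, function(col) {
      if (is.numeric(col)) matrix(col, ncol = 1)
      else {
        f <- factor(col)
        if (nlevels(f) < 2) {
          warning("constant covariate column(s) dropped")
          matrix(0, n, 0)
        } else stats::model.matrix(~ f)[, -1, drop = FALSE]
      }
    }))
    keep <- apply(cm, 2, function(col) stats::var(col) > 0)
    if (!all(keep)) warning("constant covariate column(s) dropped")
    cm <- cm[, keep, drop = FALSE]
    if (ncol(cm) == 0) cm <- NULL
  }
  ncov <- if (is.null(cm)) 0L else ncol(cm)
  .stopifnot2(n > ncov + 2, "too few observations for the covariate set")
  if (is.null(cm)) {
    rx <- x - mean(x); ry <- y - mean(y)
  } else {
    mm <- cbind(1, cm)
    rx <- stats::lm.fit(mm, x)$residuals
    ry <- stats::lm.fit(mm, y)$residuals
  }
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    warning("residual variance is zero; partial correlation undefined")
    return(list(r = NA_real_, df = n - ncov - 2L, p = NA_real_))
  }
  r <- stats::cor(rx, ry)
  df <- n - ncov - 2L
  tv <- r * sqrt(df / max(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
  list(r = r, df = df, p = p)
}

#' Hemisphere-effect scan across metrics
#'
#' Runs \code{\link{ancovaHemisphere}} for every metric in a long metrics
#' table and applies Benjamini-Hochberg correction within each
#' (modality x level) family: the 5 global metrics form one family per
#' modality, the 45 regional efficiencies another.
#'
#' @param metricsLong data.frame with columns \code{subject_id},
#'   \code{modality}, \code{hemisphere}, \code{level}, \code{metric},
#'   \code{value}.
#' @param covariates data.frame with \code{subject_id} and \code{gender}.
#' @param q FDR level.
#' @return data.frame with one row per (modality, metric): \code{F},
#'   \code{df1}, \code{df2}, \code{p}, \code{q} (BH-adjusted),
#'   \code{significant}, \code{direction}.
#' @export
hemisphereEffects <- function(metricsLong, covariates, q = 0.05) {
  need <- c("subject_id", "modality", "hemisphere", "level", "metric", "value")
  .stopifnot2(all(need %in% names(metricsLong)),
              "metricsLong is missing required columns")
  gmap <- stats::setNames(covariates$gender, covariates$subject_id)
  groups <- unique(metricsLong[, c("modality", "level", "metric")])
  res <- lapply(seq_len(nrow(groups)), function(k) {
    sub <- metricsLong[metricsLong$modality == groups$modality[k] &
                       metricsLong$metric == groups$metric[k], ]
    lv <- sub[sub$hemisphere == "L", ]
    rv <- sub[sub$hemisphere == "R", ]
    rv <- rv[match(lv$subject_id, rv$subject_id), ]
    a <- ancovaHemisphere(lv$value, rv$value,
                          gmap[as.character(lv$subject_id)])
    data.frame(modality = groups$modality[k], level = groups$level[k],
               metric = groups$metric[k], F = a$F, df1 = a$df[1],
               df2 = a$df[2], p = a$p, direction = a$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  out$significant <- FALSE
  for (fam in split(seq_len(nrow(out)),
                    paste(out$modality, out$level))) {
    ok <- fam[!is.na(out$p[fam])]
    if (!length(ok)) next
    bh <- fdrBh(out$p[ok], q)
    out$q[ok] <- bh$adjusted
    out$significant[ok] <- bh$rejected
  }
  rownames(out) <- NULL
  out
}

#' Asymmetry-behavior association scan
#'
#' Partial correlation between each selected asymmetry score and every
#' behavioral score, adjusted for age, gender, handedness and years of
#' education.  Results are reported with uncorrected p at the chosen
#' threshold and flagged as exploratory; an optional BH adjustment across
#' the scan can be requested.
#'
#' @param asTable data.frame with columns \code{subject_id}, \code{modality},
#'   \code{metric}, \code{AS}.
#' @param behavior data.frame with \code{subject_id} and one column per
#'   behavioral score.
#' @param covariates data.frame with \code{subject_id}, \code{age},
#'   \code{gender}, \code{handedness}, \code{education}.
#' @param selection data.frame with columns \code{modality}, \code{metric}:
#'   the metrics with a significant hemisphere effect.  Empty selection
#'   returns an empty table.
#' @param alpha significance threshold for the uncorrected p.
#' @param fdr apply BH across all (metric, score) pairs instead.
#' @return data.frame with one row per (modality, metric, score): \code{r},
#'   \code{df}, \code{p}, \code{significant}, \code{exploratory = TRUE}.
#' @export
associationScan <- function(asTable, behavior, covariates, selection,
                            alpha = 0.05, fdr = FALSE) {
  if (is.null(selection) || nrow(selection) == 0)
    return(data.frame(modality = character(0), metric = character(0),
                      score = character(0), r = numeric(0), df = integer(0),
                      p = numeric(0), significant = logical(0),
                      exploratory = logical(0)))
  scores <- setdiff(names(behavior), "subject_id")
  rows <- list()
  for (k in seq_len(nrow(selection))) {
    sub <- asTable[asTable$modality == selection$modality[k] &
                   asTable$metric == selection$metric[k], ]
    ids <- sub$subject_id
    miss <- setdiff(ids, intersect(behavior$subject_id,
                                   covariates$subject_id))
    if (length(miss))
      stop("subjects missing from behavior/covariate tables: ",
           paste(utils::head(miss, 5), collapse = ", "))
    beh <- behavior[match(ids, behavior$subject_id), , drop = FALSE]
    cov <- covariates[match(ids, covariates$subject_id),
                      c("age", "gender", "handedness", "education")]
    for (sc in scores) {
      pc <- suppressWarnings(
        partialCorrelation(sub$AS, beh[[sc]], cov))
      rows[[length(rows) + 1L]] <- data.frame(
        modality = selection$modality[k], metric = selection$metric[k],
        score = sc, r = pc$r, df = pc$df, p = pc$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (fdr) {
    bh <- fdrBh(out$p, alpha)
    out$significant <- bh$rejected
  } else {
    out$significant <- !is.na(out$p) & out$p < alpha
  }
  out$exploratory <- TRUE
  rownames(out) <- NULL
  out
}
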