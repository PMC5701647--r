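#' Hemispheric networks for every subject of a cohort
#'
#' Builds the whole-brain connectomes (functional connectivity from the
#' simulated/observed time series; structural networks as provided) and
#' splits each into homotopically aligned left/right intrahemispheric
#' networks.
#'
#' @param cb a \code{CohortBundle} from \code{\link{simulateCohort}}.
#' @param modalities subset of \code{c("structural", "functional")}.
#' @return List per subject with, per requested modality, a list
#'   \code{L}/\code{R} of unthresholded \linkS4class{HemiNetwork}s.
#' @export
buildCohortNetworks <- function(cb,
                                modalities = c("structural", "functional")) {
  lapply(cb$subjects, function(s) {
    out <- list(subjectId = s$subjectId)
    if ("structural" %in% modalities)
      out$structural <- splitHemispheres(s$structural, cb$nodeTable)
    if ("functional" %in% modalities) {
      fc <- functionalConnectivity(s$timeseries, subjectId = s$subjectId)
      out$functional <- splitHemispheres(fc, cb$nodeTable)
    }
    out
  })
}

# metrics for one subject x modality; returns list(L = metrics, R = metrics)
.subjectModalityMetrics <- function(hemis, modality, sparsity, nNull, seed) {
  norm <- normalizeWeightsJoint(hemis$L, hemis$R)
  if (modality == "structural") {
    list(L = hemiMetrics(norm$L, nNull = nNull, seed = .deriveSeed(seed, 1L)),
         R = hemiMetrics(norm$R, nNull = nNull, seed = .deriveSeed(seed, 2L)))
  } else {
    list(L = integratedMetrics(norm$L, sparsity$min, sparsity$max,
                               sparsity$step, nNull = nNull,
                               seed = .deriveSeed(seed, 1L)),
         R = integratedMetrics(norm$R, sparsity$min, sparsity$max,
                               sparsity$step, nNull = nNull,
                               seed = .deriveSeed(seed, 2L)))
  }
}

.globalMetricNames <- c("Cw", "Lw", "sigma", "Eglobal", "Elocal")

#' Cohort-level network metrics
#'
#' Computes, for every subject x modality x hemisphere, the weighted
#' small-world metrics: structural networks are analyzed once, unthresholded,
#' after joint max-weight normalization; functional networks are thresholded
#' over the sparsity grid and every metric integrated over the range.  Null
#' seeds are derived per (subject, hemisphere, modality) from the master
#' seed.
#'
#' @param networks output of \code{\link{buildCohortNetworks}}.
#' @param sparsity list with \code{min}, \code{max}, \code{step}.
#' @param nNull rewired nulls for the small-world indices (0 to skip).
#' @param seed master seed.
#' @return List with \code{long} (tidy data.frame: subject_id, modality,
#'   hemisphere, level, metric, value), \code{wide} (one row per
#'   subject x modality x hemisphere) and \code{raw} (nested metric lists,
#'   used by \code{\link{cohortAsymmetry}}).
#' @export
cohortMetrics <- function(networks,
                          sparsity = list(min = 0.10, max = 0.35,
                                          step = 0.01),
                          nNull = 100L, seed = 1L) {
  raw <- list()
  longRows <- list()
  wideRows <- list()
  for (i in seq_along(networks)) {
    sub <- networks[[i]]
    for (mod in intersect(c("structural", "functional"), names(sub))) {
      mm <- .subjectModalityMetrics(sub[[mod]], mod, sparsity, nNull,
                                    .deriveSeed(seed, i,
                                                match(mod, c("structural",
                                                             "functional"))))
      raw[[sub$subjectId]][[mod]] <- mm
      for (h in c("L", "R")) {
        m <- mm[[h]]
        gvals <- unlist(m[intersect(.globalMetricNames, names(m))])
        longRows[[length(longRows) + 1L]] <- data.frame(
          subject_id = sub$subjectId, modality = mod, hemisphere = h,
          level = "global", metric = names(gvals), value = unname(gvals),
          stringsAsFactors = FALSE)
        longRows[[length(longRows) + 1L]] <- data.frame(
          subject_id = sub$subjectId, modality = mod, hemisphere = h,
          level = "regional", metric = paste0("Enodal_", names(m$Enodal)),
          value = unname(m$Enodal), stringsAsFactors = FALSE)
        wr <- data.frame(subject_id = sub$subjectId, modality = mod,
                         hemisphere = h, stringsAsFactors = FALSE)
        for (g in c("Cw", "Lw", "gamma", "lambda", "sigma", "Eglobal",
                    "Elocal"))
          wr[[g]] <- if (is.null(m[[g]])) NA_real_ else m[[g]]
        wr$n_unreachable_pairs <- m$nUnreachablePairs
        en <- as.data.frame(as.list(m$Enodal))
        names(en) <- paste0("Enodal_", names(m$Enodal))
        wideRows[[length(wideRows) + 1L]] <- cbind(wr, en)
      }
    }
  }
  list(long = do.call(rbind, longRows), wide = do.call(rbind, wideRows),
       raw = raw)
}

#' Cohort-level asymmetry table
#'
#' One AS(X) score per subject, modality and metric (5 global + 45
#' regional), from the per-hemisphere metric lists.
#'
#' @param metrics output of \code{\link{cohortMetrics}}.
#' @return data.frame (see \code{\link{subjectAsymmetryProfile}}).
#' @export
cohortAsymmetry <- function(metrics) {
  rows <- list()
  for (sid in names(metrics$raw)) {
    for (mod in names(metrics$raw[[sid]])) {
      mm <- metrics$raw[[sid]][[mod]]
      rows[[length(rows) + 1L]] <-
        subjectAsymmetryProfile(mm$L, mm$R, subjectId = sid, modality = mod)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.nbsToList <- function(res, labels) {
  compOut <- function(comps) lapply(comps, function(co) {
    list(size = co$size,
         p = co$p,
         nodes = labels[co$nodes],
         edges = apply(co$edges, 1, function(e)
           paste(labels[e[1]], labels[e[2]], sep = "--")))
  })
  list(tThreshold = res@tThreshold, nPerm = res@nPerm,
       exhaustive = res@exhaustive, seed = res@seed,
       components = list(positive = compOut(res@components$positive),
                         negative = compOut(res@components$negative)),
       nullMaxSizes = list(positive = as.integer(res@nullMaxSizes[, 1]),
                           negative = as.integer(res@nullMaxSizes[, 2])))
}

#' Run the full analysis pipeline
#'
#' Chains simulate, build, metrics, asymmetry, NBS and group statistics on a
#' synthetic cohort, writing every artifact (TSV matrices and tables, NBS
#' JSON, truth block) plus a manifest recording the package version, master
#' seed, configuration hash and per-file MD5 checksums.  Deterministic: the
#' same configuration and seed produce byte-identical outputs and manifest.
#'
#' @param outDir output directory (created if needed).
#' @param config pipeline configuration (\code{\link{pipelineConfig}}).
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(outDir, config = pipelineConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  seed <- config$seed
  ver <- as.character(utils::packageVersion("hemiconn"))
  meta <- list(tool = paste0("hemiconn ", ver), seed = seed)
  files <- character(0)
  put <- function(name) files <<- c(files, name)
  message("[simulate] generating cohort of ", config$nSubjects, " subjects")
  cb <- stage("simulate",
              simulateCohort(config$nSubjects, config$cohort, seed = seed))
  stage("simulate", {
    writeNodeTable(cb$nodeTable, file.path(outDir, "node_table.tsv"), meta)
    put("node_table.tsv")
    .writeTableTSV(cb$covariates, file.path(outDir, "cohort.tsv"), meta)
    put("cohort.tsv")
    .writeTableTSV(cb$behavior, file.path(outDir, "behavior.tsv"), meta)
    put("behavior.tsv")
    jsonlite::write_json(cb$truth, file.path(outDir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    put("truth.json")
    for (s in cb$subjects) {
      if ("structural" %in% config$modalities) {
        f <- sprintf("structural_%s.tsv", s$subjectId)
        writeMatrixTSV(weights(s$structural), file.path(outDir, f), meta)
        put(f)
      }
      if ("functional" %in% config$modalities) {
        f <- sprintf("timeseries_%s.tsv", s$subjectId)
        .writeTableTSV(as.data.frame(s$timeseries), file.path(outDir, f),
                       meta)
        put(f)
      }
    }
  })
  message("[build] constructing hemispheric networks")
  networks <- stage("build", buildCohortNetworks(cb, config$modalities))
  message("[metrics] weighted small-world metrics (nNull = ",
          config$nNull, ")")
  metrics <- stage("metrics",
                   cohortMetrics(networks, config$sparsity, config$nNull,
                                 seed = .deriveSeed(seed, 101L)))
  stage("metrics", {
    .writeTableTSV(metrics$wide, file.path(outDir, "metrics.tsv"), meta)
    put("metrics.tsv")
  })
  message("[asymmetry] AS(X) laterality scores")
  asym <- stage("asymmetry", cohortAsymmetry(metrics))
  stage("asymmetry", {
    .writeTableTSV(asym, file.path(outDir, "asymmetry.tsv"), meta)
    put("asymmetry.tsv")
  })
  message("[nbs] paired network-based statistic")
  abbr <- .pairAbbr(cb$nodeTable)
  for (mod in config$modalities) {
    res <- stage("nbs", {
      ls <- lapply(networks, function(s) s[[mod]]$L)
      rs <- lapply(networks, function(s) s[[mod]]$R)
      nbsPaired(ls, rs, tThreshold = config$nbs$tThreshold,
                nPerm = config$nbs$nPerm,
                seed = .deriveSeed(seed, 201L, match(mod, config$modalities)))
    })
    f <- sprintf("nbs_%s.json", mod)
    ft <- sprintf("nbs_tmap_%s.tsv", mod)
    stage("nbs", {
      out <- .nbsToList(res, abbr)
      out$tMapFile <- ft
      jsonlite::write_json(out, file.path(outDir, f), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      writeMatrixTSV(res@tMap, file.path(outDir, ft), meta)
    })
    put(f); put(ft)
  }
  message("[stats] hemisphere effects and behavior associations")
  stats <- stage("stats", {
    he <- hemisphereEffects(metrics$long, cb$covariates, q = config$fdrQ)
    sel <- he[he$significant, c("modality", "metric")]
    assoc <- associationScan(asym, cb$behavior, cb$covariates, sel,
                             alpha = config$alpha)
    list(hemisphere = he, association = assoc)
  })
  stage("stats", {
    .writeTableTSV(stats$hemisphere,
                   file.path(outDir, "stats_hemisphere.tsv"), meta)
    put("stats_hemisphere.tsv")
    .writeTableTSV(stats$association,
                   file.path(outDir, "stats_association.tsv"), meta)
    put("stats_association.tsv")
  })
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(as.character(cfgJson), tmp)
  cfgHash <- unname(tools::md5sum(tmp)); unlink(tmp)
  sums <- tools::md5sum(file.path(outDir, sort(files)))
  names(sums) <- sort(files)
  manifest <- list(package = "hemiconn", version = ver, seed = seed,
                   configHash = cfgHash, config = config,
                   files = as.list(sums))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Verify pipeline output checksums
#'
#' Recomputes the MD5 checksum of every file recorded in a run's manifest
#' and reports mismatches (e.g. tampered or truncated intermediates).
#'
#' @param outDir pipeline output directory containing \code{manifest.json}.
#' @return List with \code{ok} (logical) and \code{mismatches} (character
#'   vector of file names).
#' @export
verifyManifest <- function(outDir) {
  manifest <- jsonlite::read_json(file.path(outDir, "manifest.json"))
  files <- names(manifest$files)
  cur <- tools::md5sum(file.path(outDir, files))
  bad <- files[is.na(cur) | cur != unlist(manifest$files)]
  list(ok = length(bad) == 0, mismatches = bad)
}
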