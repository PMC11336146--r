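## Pipeline driver and publication-style figure/table emission.

openDevice <- function(path, width = 7, height = 7) {
  if (grepl("\\.svg$", path, ignore.case = TRUE))
    grDevices::svg(path, width = width, height = height)
  else if (grepl("\\.png$", path, ignore.case = TRUE))
    grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  else stopf("unsupported figure format: %s (use .svg or .png)", path)
}

## deterministic TSV emission: fixed number formatting, no quoting
writeReportTable <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x)
    ifelse(is.na(x), NA, format(x, digits = 12, trim = TRUE)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

drawKMPanel <- function(time, event, group, annotation = NULL,
                        main = "Kaplan-Meier", atRiskTimes = NULL,
                        xlab = "Time (months)", cex_annot = 0.9) {
  g <- as.factor(group)
  levs <- levels(droplevels(g))
  cols <- c("black", "red", "blue", "darkgreen")[seq_along(levs)]
  xmax <- max(time)
  plot(NA, xlim = c(0, xmax), ylim = c(0, 1.02), xlab = xlab,
       ylab = "Survival probability", main = main)
  for (i in seq_along(levs)) {
    sel <- g == levs[i]
    km <- kmEstimate(time[sel], event[sel], conf = FALSE)
    sx <- c(0, rep(km$time, each = 2), xmax)
    sy <- c(1, 1, rep(km$survival, each = 2))
    graphics::lines(sx, sy[seq_along(sx)], col = cols[i], lwd = 2)
    cens <- time[sel][event[sel] == 0]
    surv_at <- vapply(cens, function(tt) {
      s <- km$survival[km$time <= tt]
      if (length(s)) s[length(s)] else 1
    }, numeric(1))
    graphics::points(cens, surv_at, pch = 3, cex = 0.5, col = cols[i])
  }
  graphics::legend("bottomleft", legend = levs, col = cols, lwd = 2, bty = "n",
                   cex = cex_annot)
  if (!is.null(annotation))
    graphics::mtext(annotation, side = 3, line = -1.5, adj = 0.98,
                    cex = cex_annot)
  if (!is.null(atRiskTimes)) {
    at_risk <- vapply(levs, function(l) {
      vapply(atRiskTimes, function(tt) sum(time[g == l] >= tt), numeric(1))
    }, numeric(length(atRiskTimes)))
    graphics::mtext("At risk:", side = 1, line = 2.8, adj = 0, cex = 0.7)
    for (i in seq_along(levs))
      graphics::mtext(paste(at_risk[, i], collapse = "   "), side = 1,
                      line = 2.8 + i * 0.8, at = mean(range(atRiskTimes)),
                      cex = 0.7, col = cols[i])
  }
}

#' Render an annotated Kaplan-Meier figure
#'
#' Draws step survival curves per group with censoring ticks, a legend,
#' at-risk counts beneath the axis and an optional HR/CI/p annotation,
#' written as SVG or PNG.
#'
#' @param time,event survival outcome.
#' @param group group labels (one curve per level; a single level gives a
#'   single unannotated curve).
#' @param annotation optional text (e.g. \code{"HR = 2.7 (2.1-3.5), p = 6.4e-16"}).
#' @param path output file (.svg/.png); \code{NULL} draws on the current
#'   device.
#' @param main plot title.
#' @return the path, invisibly.
#' @export
renderKM <- function(time, event, group = rep("all", length(time)),
                     annotation = NULL, path = NULL, main = "Kaplan-Meier") {
  checkSurv(time, event)
  if (length(group) != length(time)) stopf("'group' misaligned with 'time'")
  if (!is.null(path)) {
    openDevice(path, width = 7, height = 6.5)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mar = c(8, 4, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  drawKMPanel(time, event, group, annotation, main,
              atRiskTimes = pretty(c(0, max(time)), n = 5))
  invisible(path)
}

#' Render a per-dataset grid of Kaplan-Meier panels
#'
#' One annotated panel per retained dataset (HR and p in the corner),
#' the layout used to show dataset-wise replication of a signature.
#'
#' @param cohort a \code{SurvCohort}.
#' @param weights shared \linkS4class{GeneWeights}.
#' @param datasetResults result of [perDataset()].
#' @param path output file (.svg/.png).
#' @return the path, invisibly.
#' @export
renderKMGrid <- function(cohort, weights, datasetResults, path = NULL) {
  k <- nrow(datasetResults)
  if (!k) stopf("empty dataset result")
  nc <- ceiling(sqrt(k)); nr <- ceiling(k / nc)
  if (!is.null(path)) {
    openDevice(path, width = 3.5 * nc, height = 3.2 * nr)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(op), add = TRUE)
  cd <- colData(cohort)
  for (i in seq_len(k)) {
    row <- datasetResults[i, ]
    sel <- cd$dataset_id == row$dataset_id
    scores <- scoreSamples(cohort[, sel], weights)
    hi <- ifelse(scores > row$cutoff, "high", "low")
    drawKMPanel(cd$time[sel], cd$event[sel], hi,
                annotation = sprintf("HR = %.2f, p = %s", row$hr,
                                     formatP(row$p)),
                main = row$dataset_id, cex_annot = 0.7)
  }
  invisible(path)
}

mergeConfig <- function(defaults, override) {
  for (nm in names(override)) defaults[[nm]] <- override[[nm]]
  defaults
}

#' Run the full signature pipeline
#'
#' Executes the end-to-end analysis — cohort acquisition (simulation or
#' files), scaling normalization, clinical summary, gene screening (or a
#' fixed signature), scoring, the quartile cutoff scan, Kaplan-Meier
#' rendering at the selected cutoff, per-dataset replication and the
#' paired bivariate Cox loop — writing every table as TSV plus SVG
#' figures, a manifest of MD5 content hashes and an echo of the exact
#' configuration. Tables are byte-identical across re-runs with the same
#' config and seed. Any stage error aborts with the failing stage named.
#'
#' @param config a named list, or path to a YAML file with the same
#'   structure. Recognized fields: \code{outdir} (required), \code{seed}
#'   (default 1), \code{simulate} (logical or list of [simConfig()]
#'   overrides; default \code{TRUE}), \code{input} (list with
#'   \code{expression}, \code{clinical}, \code{orientation},
#'   \code{gene_list} paths — used when \code{simulate} is
#'   \code{FALSE}), \code{normalize} (default \code{TRUE}),
#'   \code{target_mean} (1000), \code{scan} (list: \code{q_low},
#'   \code{q_high}, \code{min_group}, \code{test}), \code{per_dataset}
#'   (list: \code{min_n}, \code{min_events}), \code{figures} (logical,
#'   default \code{TRUE}).
#' @return invisible list with the in-memory results (\code{cohort},
#'   \code{analysis}, \code{perDataset}, \code{paired},
#'   \code{manifest}).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$outdir)) stopf("config must name an 'outdir'")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  figures <- !isFALSE(config$figures)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  ## --- acquire cohort -----------------------------------------------------
  truth <- NULL
  if (!isFALSE(config$simulate)) {
    cohort <- stage("simulate", {
      overrides <- if (is.list(config$simulate)) config$simulate else list()
      overrides$seed <- seed
      cfg <- do.call(simConfig, overrides)
      sim <- simulateCohort(cfg)
      truth <- sim$truth
      clin <- simulateClinicalCovariates(clinicalData(sim$cohort),
                                         seed = seed + 1L)
      SurvCohort(assay(sim$cohort, "exprs"), clin)
    })
  } else {
    cohort <- stage("load_inputs", {
      inp <- config$input
      if (is.null(inp$expression) || is.null(inp$clinical))
        stopf("input$expression and input$clinical are required")
      expr <- readExpression(inp$expression,
                             orientation = if (is.null(inp$orientation))
                               "samples_by_genes" else inp$orientation)
      clin <- readClinical(inp$clinical)
      SurvCohort(expr, clin)
    })
  }
  if (!isFALSE(config$normalize)) {
    cohort <- stage("normalize", scaleNormalize(
      cohort, if (is.null(config$target_mean)) 1000 else config$target_mean))
    logMsg("normalize", samples = ncol(cohort))
  }
  clin <- clinicalData(cohort)
  stage("clinical_summary",
        writeReportTable(clinicalSummary(clin),
                         file.path(outdir, "clinical_summary.tsv")))

  ## --- signature ----------------------------------------------------------
  weights <- stage("signature", {
    if (!is.null(config$input$gene_list) && isFALSE(config$simulate)) {
      gl <- readGeneList(config$input$gene_list)
      if (all(!is.na(gl$fixed_weight))) fixedSignature(gl)
      else screenGenes(cohort, genes = gl$gene_id)
    } else screenGenes(cohort)
  })
  writeGeneWeights(weights, file.path(outdir, "weights.tsv"))

  ## --- score / scan / KM --------------------------------------------------
  scan_args <- if (is.list(config$scan)) config$scan else list()
  analysis <- stage("scan", do.call(analyzeCohort, c(
    list(cohort = cohort, weights = weights),
    scan_args[intersect(names(scan_args),
                        c("qLow", "qHigh", "minGroup", "test"))])))
  writeReportTable(data.frame(sample_id = names(analysis$scores),
                              score = analysis$scores,
                              group = ifelse(analysis$groups, "high", "low")),
                   file.path(outdir, "scores.tsv"))
  writeReportTable(scanTable(analysis$scan), file.path(outdir, "scan.tsv"))
  writeReportTable(scanProfile(analysis$scan), file.path(outdir, "profile.tsv"))
  sel <- selectedCutoff(analysis$scan)
  writeReportTable(
    data.frame(term = "signature_high_vs_low", cutoff = sel$cutoff,
               hr = analysis$cox$hr, ci_low = analysis$cox$ci_low,
               ci_high = analysis$cox$ci_high, p = analysis$cox$p,
               p_adj = sel$p_adj, logrank_p = analysis$logrank$p,
               n = analysis$cox$n, events = analysis$cox$events),
    file.path(outdir, "signature_cox.tsv"))
  if (figures) {
    stage("km_figure", {
      renderKM(clin$time, clin$event,
               ifelse(analysis$groups, "high", "low"),
               annotation = sprintf("HR = %.2f (%.2f-%.2f), p = %s",
                                    analysis$cox$hr, analysis$cox$ci_low,
                                    analysis$cox$ci_high,
                                    formatP(analysis$cox$p)),
               path = file.path(outdir, "km_overall.svg"),
               main = "Signature (high vs low)")
      plotScanProfile(analysis$scan, file.path(outdir, "scan_profile.svg"))
    })
  }

  ## --- per-dataset replication -------------------------------------------
  pd_args <- if (is.list(config$per_dataset)) config$per_dataset else list()
  pd <- stage("per_dataset", do.call(perDataset, c(
    list(cohort = cohort, weights = weights),
    list(minN = if (is.null(pd_args$min_n)) 30L else pd_args$min_n,
         minEvents = if (is.null(pd_args$min_events)) 10L else
           pd_args$min_events))))
  writeReportTable(pd, file.path(outdir, "per_dataset.tsv"))
  writeReportTable(attr(pd, "excluded"),
                   file.path(outdir, "per_dataset_excluded.tsv"))
  if (figures)
    stage("km_grid", renderKMGrid(cohort, weights, pd,
                                  file.path(outdir, "per_dataset_km.svg")))

  ## --- paired multivariate ------------------------------------------------
  paired <- stage("multivariate", tryCatch(
    pairedMultivariateAll(analysis$scores, clin, sel$cutoff),
    error = function(e) {
      logMsg("multivariate", skipped = "no_covariates")
      NULL
    }))
  if (!is.null(paired))
    writeReportTable(paired, file.path(outdir, "paired_multivariate.tsv"))

  if (!is.null(truth))
    writeReportTable(truth, file.path(outdir, "truth.tsv"))

  ## --- manifest + config echo ---------------------------------------------
  yaml::write_yaml(config, file.path(outdir, "config_echo.yaml"))
  tsvs <- sort(list.files(outdir, pattern = "\\.(tsv|yaml)$"))
  manifest <- data.frame(file = tsvs,
                         md5 = unname(tools::md5sum(file.path(outdir, tsvs))))
  writeReportTable(manifest, file.path(outdir, "manifest.tsv"))
  logMsg("pipeline", status = "complete", outdir = outdir)
  invisible(list(cohort = cohort, weights = weights, analysis = analysis,
                 perDataset = pd, paired = paired, truth = truth,
                 manifest = manifest))
}
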