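#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   colData rowData
NULL

#' Survival cohort container
#'
#' A \code{SurvCohort} couples a nonnegative gene-level expression matrix
#' (genes in rows, samples in columns, MAS5-scale linear intensities) with
#' per-sample relapse-free survival annotation. It extends
#' \linkS4class{SummarizedExperiment}; the expression matrix is the
#' \code{"exprs"} assay and the clinical table lives in \code{colData},
#' which must contain at least \code{time} (months, strictly positive),
#' \code{event} (0 = censored, 1 = relapse) and \code{dataset_id}
#' (the originating dataset, used for per-dataset replication).
#' Clinical covariates (\code{sex}, \code{t_stage}, \code{n_stage},
#' \code{m_stage}, \code{stage}, \code{grade}, \code{location}, \code{msi})
#' are optional and may contain \code{NA}; they are never imputed.
#'
#' @seealso [SurvCohort()] for the validating constructor.
#' @export
setClass("SurvCohort", contains = "SummarizedExperiment")

setValidity("SurvCohort", function(object) {
  msg <- character()
  if (!"exprs" %in% names(assays(object)))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    x <- assay(object, "exprs")
    if (!is.numeric(x)) msg <- c(msg, "'exprs' must be numeric")
    else if (any(!is.finite(x))) msg <- c(msg, "'exprs' contains non-finite values")
    else if (any(x < 0)) msg <- c(msg, "'exprs' contains negative intensities")
    if (ncol(x) < 2L) msg <- c(msg, "at least 2 samples are required")
    if (nrow(x) < 1L) msg <- c(msg, "at least 1 gene is required")
    if (anyDuplicated(rownames(x))) msg <- c(msg, "duplicated gene ids")
    if (anyDuplicated(colnames(x))) msg <- c(msg, "duplicated sample ids")
  }
  cd <- colData(object)
  for (col in c("time", "event", "dataset_id"))
    if (!col %in% colnames(cd)) msg <- c(msg, sprintf("colData column '%s' is required", col))
  if ("time" %in% colnames(cd) && any(!is.finite(cd$time) | cd$time <= 0))
    msg <- c(msg, "'time' must be strictly positive and finite")
  if ("event" %in% colnames(cd) && !all(cd$event %in% c(0, 1)))
    msg <- c(msg, "'event' must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Per-gene hazard directions defining a signature
#'
#' A \code{GeneWeights} object is the fitted (or fixed) definition of a
#' weighted signature: one row per gene with the univariate Cox hazard
#' ratio, its 95\% confidence interval and Wald p-value (all \code{NA}
#' for a fixed signature loaded from a gene list), the \code{weight}
#' in \{-1, 0, +1\} assigned from the hazard-ratio direction (+1 when
#' HR > 1, -1 when 0 < HR < 1, 0 when the fit is degenerate), and the
#' \code{source} of each row (\code{"fitted"} or \code{"fixed"}).
#'
#' @slot table a \code{DataFrame} with columns \code{gene_id}, \code{hr},
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{weight}, \code{source},
#'   \code{reason} (why a gene got weight 0, otherwise \code{NA}).
#' @seealso [screenGenes()], [fixedSignature()], [scoreSamples()]
#' @export
setClass("GeneWeights", representation(table = "DataFrame"))

setValidity("GeneWeights", function(object) {
  tb <- object@table
  need <- c("gene_id", "hr", "ci_low", "ci_high", "p", "weight", "source")
  msg <- character()
  if (!all(need %in% colnames(tb)))
    msg <- c(msg, paste("missing columns:", paste(setdiff(need, colnames(tb)), collapse = ", ")))
  else {
    if (anyDuplicated(tb$gene_id)) msg <- c(msg, "duplicated gene ids")
    if (!all(tb$weight %in% c(-1, 0, 1))) msg <- c(msg, "weights must be -1, 0 or +1")
    if (!all(tb$source %in% c("fitted", "fixed"))) msg <- c(msg, "source must be 'fitted' or 'fixed'")
    fitted <- tb$source == "fitted" & !is.na(tb$hr)
    bad <- fitted & ((tb$hr > 1 & tb$weight != 1) | (tb$hr < 1 & tb$weight != -1) |
                       (tb$hr == 1 & tb$weight != 0))
    if (any(bad)) msg <- c(msg, "weight inconsistent with hazard-ratio direction")
    if (any(tb$source == "fixed" & tb$weight == 0))
      msg <- c(msg, "fixed weights must be -1 or +1")
  }
  if (length(msg)) msg else TRUE
})

#' Result of an exhaustive cutoff scan
#'
#' Holds the per-cutoff dichotomized survival tests of a signature score:
#' every unique observed score between the lower and upper quartiles is
#' tried as a cutoff (low group: score <= cutoff; high group: score >
#' cutoff), each yielding a hazard ratio (high vs low) and p-value, with
#' Benjamini-Hochberg adjustment across the scanned family. The selected
#' cutoff minimizes the raw p-value (ties broken toward the median score).
#'
#' @slot table \code{DataFrame} with columns \code{cutoff}, \code{hr},
#'   \code{p}, \code{p_adj}, \code{n_low}, \code{n_high}.
#' @slot selected named list: \code{cutoff}, \code{p}, \code{p_adj},
#'   \code{hr}, \code{hr_range} (min/max over scanned cutoffs).
#' @slot scores the scanned signature scores (named by sample).
#' @seealso [scanCutoffs()], [scanProfile()]
#' @export
setClass("CutoffScan",
         representation(table = "DataFrame", selected = "list",
                        scores = "numeric"))

setValidity("CutoffScan", function(object) {
  tb <- object@table
  msg <- character()
  if (nrow(tb) < 1L) msg <- c(msg, "empty scan")
  if (is.unsorted(tb$cutoff, strictly = TRUE)) msg <- c(msg, "cutoffs must be strictly increasing")
  if (any(tb$p_adj + 1e-12 < tb$p)) msg <- c(msg, "adjusted p below raw p")
  n <- length(object@scores)
  if (any(tb$n_low + tb$n_high != n)) msg <- c(msg, "group sizes do not partition the cohort")
  sel <- object@selected
  if (!is.null(sel$p) && abs(sel$p - min(tb$p)) > 1e-12)
    msg <- c(msg, "selected p is not the scan minimum")
  if (length(msg)) msg else TRUE
})

#' @describeIn SurvCohort-class construct a validated cohort from an
#'   expression matrix (genes x samples) and a clinical table; samples are
#'   matched by id and must agree one-to-one.
#' @param exprs numeric matrix, genes in rows, samples in columns, with
#'   dimnames; nonnegative finite intensities.
#' @param clinical data.frame with \code{sample_id}, \code{time},
#'   \code{event}, \code{dataset_id} and optional covariate columns.
#' @return a \code{SurvCohort}.
#' @examples
#' expr <- matrix(c(100, 200, 300, 400, 500, 600), nrow = 2,
#'                dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' clin <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                    time = c(12, 30, 45), event = c(1, 0, 0),
#'                    dataset_id = "d1")
#' SurvCohort(expr, clin)
#' @export
SurvCohort <- function(exprs, clinical) {
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stopf("'exprs' must carry gene row names and sample column names")
  if (!is.data.frame(clinical) && !is(clinical, "DataFrame"))
    stopf("'clinical' must be a data.frame")
  clinical <- as.data.frame(clinical)
  if (!"sample_id" %in% colnames(clinical))
    stopf("'clinical' must contain a 'sample_id' column")
  if (anyDuplicated(clinical$sample_id))
    stopf("duplicated sample ids in clinical table")
  missing <- setdiff(colnames(exprs), clinical$sample_id)
  if (length(missing))
    stopf("samples without clinical records: %s",
          paste(head(missing, 5L), collapse = ", "))
  clinical <- clinical[match(colnames(exprs), clinical$sample_id), , drop = FALSE]
  cd <- DataFrame(clinical[setdiff(colnames(clinical), "sample_id")],
                  row.names = clinical$sample_id)
  new("SurvCohort",
      SummarizedExperiment(assays = list(exprs = exprs), colData = cd))
}

#' @describeIn SurvCohort-class the survival annotation as a plain
#'   data.frame (sample_id, time, event, dataset_id, covariates).
#' @param cohort a \code{SurvCohort}.
#' @export
clinicalData <- function(cohort) {
  stopifnot(is(cohort, "SurvCohort"))
  cd <- as.data.frame(colData(cohort))
  data.frame(sample_id = rownames(cd), cd, row.names = NULL,
             check.names = FALSE)
}

#' @describeIn GeneWeights-class the weight table as a data.frame.
#' @param object a \code{GeneWeights}.
#' @export
weightTable <- function(object) {
  stopifnot(is(object, "GeneWeights"))
  as.data.frame(object@table)
}

#' @describeIn CutoffScan-class the per-cutoff table as a data.frame.
#' @param object a \code{CutoffScan}.
#' @export
scanTable <- function(object) {
  stopifnot(is(object, "CutoffScan"))
  as.data.frame(object@table)
}

#' @describeIn CutoffScan-class the selected cutoff and its statistics.
#' @export
selectedCutoff <- function(object) {
  stopifnot(is(object, "CutoffScan"))
  object@selected
}

setMethod("show", "SurvCohort", function(object) {
  cat(sprintf("SurvCohort: %d genes x %d samples, %d dataset(s), %d events (%.1f%%)\n",
              nrow(object), ncol(object),
              length(unique(colData(object)$dataset_id)),
              sum(colData(object)$event),
              100 * mean(colData(object)$event)))
  callNextMethod()
})

setMethod("show", "GeneWeights", function(object) {
  tb <- object@table
  cat(sprintf("GeneWeights: %d genes (%d risk [+1], %d protective [-1], %d excluded [0]); source: %s\n",
              nrow(tb), sum(tb$weight == 1), sum(tb$weight == -1),
              sum(tb$weight == 0), paste(unique(tb$source), collapse = "/")))
})

setMethod("show", "CutoffScan", function(object) {
  sel <- object@selected
  cat(sprintf("CutoffScan: %d cutoffs scanned in [Q1, Q3); selected cutoff %.4g (HR = %.3g, p = %.2g, FDR = %.2g)\n",
              nrow(object@table), sel$cutoff, sel$hr, sel$p, sel$p_adj))
  cat(sprintf("  HR range over scan: %.3g - %.3g\n",
              sel$hr_range[1], sel$hr_range[2]))
})
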