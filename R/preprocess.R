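## Scaling normalization, platform restriction, probe->gene collapse and
## array-level quality flagging.

#' Per-array scaling normalization
#'
#' Rescales every sample (column) linearly so its mean intensity over
#' genes equals \code{targetMean} — the scaling step applied to MAS5-style
#' microarray intensities to make arrays comparable, with the conventional
#' target mean of 1000. Per-sample gene rank order is unchanged; the
#' operation is idempotent.
#'
#' @param x genes x samples numeric matrix, or a \code{SurvCohort}.
#' @param targetMean target per-sample mean intensity (default 1000).
#' @return object of the same class with every sample mean equal to
#'   \code{targetMean} (relative error below 1e-9).
#' @examples
#' m <- matrix(c(1, 2, 3), nrow = 3, dimnames = list(paste0("g", 1:3), "s1"))
#' scaleNormalize(cbind(m, s2 = c(10, 30, 20)))
#' @export
scaleNormalize <- function(x, targetMean = 1000) {
  assertNumericScalar(targetMean, "targetMean")
  if (targetMean <= 0) stopf("'targetMean' must be positive")
  if (is(x, "SurvCohort")) {
    assay(x, "exprs") <- scaleNormalize(assay(x, "exprs"), targetMean)
    validObject(x)
    return(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) stopf("'x' must be a numeric matrix")
  if (any(x < 0)) stopf("negative intensities are not allowed")
  mu <- colMeans(x)
  if (any(mu <= 0)) {
    bad <- colnames(x)[which(mu <= 0)[1]]
    stopf("sample '%s' has non-positive mean intensity; cannot scale",
          if (is.null(bad)) as.character(which(mu <= 0)[1]) else bad)
  }
  sweep(x, 2L, targetMean / mu, "*")
}

#' Restrict a probe-level matrix to a platform's probes
#'
#' Keeps only rows whose probe ids are on the given platform, preserving
#' their original order — the harmonization step when integrating arrays
#' from platforms that share a probe subset (e.g. restricting larger
#' arrays to the probes of the smallest common platform).
#'
#' @param exprs probes x samples matrix with probe row names.
#' @param platformProbes character vector of platform probe ids.
#' @return the row-subset matrix; the number of dropped probes is
#'   reported via \code{message()} and attached as attribute
#'   \code{"dropped"}.
#' @export
restrictProbes <- function(exprs, platformProbes) {
  if (!length(platformProbes)) stopf("'platformProbes' is empty")
  if (is.null(rownames(exprs))) stopf("'exprs' must have probe row names")
  keep <- rownames(exprs) %in% platformProbes
  if (!any(keep)) stopf("no probes in common with the platform")
  dropped <- sum(!keep)
  logMsg("restrict_probes", kept = sum(keep), dropped = dropped)
  out <- exprs[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Collapse probe-level expression to gene level
#'
#' Maps probes to genes using a chosen-probe table (one best probe per
#' gene, as produced by probe-ranking methods such as JetSet): each gene's
#' expression is taken from its single chosen probe — no averaging — so
#' every output value is present in the input. Genes whose chosen probe is
#' absent from the matrix are omitted with a logged count.
#'
#' @param exprs probes x samples matrix.
#' @param probeMap data.frame with columns \code{probe_id},
#'   \code{gene_id}, \code{chosen} (logical).
#' @return genes x samples matrix.
#' @export
collapseToGenes <- function(exprs, probeMap) {
  need <- c("probe_id", "gene_id", "chosen")
  if (!all(need %in% colnames(probeMap)))
    stopf("probe map needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(probeMap$probe_id))
    stopf("duplicated probe id(s) in map: %s",
          paste(unique(probeMap$probe_id[duplicated(probeMap$probe_id)]),
                collapse = ", "))
  chosen <- probeMap[as.logical(probeMap$chosen), , drop = FALSE]
  if (anyDuplicated(chosen$gene_id))
    stopf("more than one chosen probe for gene(s): %s",
          paste(unique(chosen$gene_id[duplicated(chosen$gene_id)]),
                collapse = ", "))
  present <- chosen$probe_id %in% rownames(exprs)
  if (!any(present)) stopf("no chosen probe of the map is present in 'exprs'")
  if (any(!present))
    logMsg("collapse_to_genes", genes_dropped_absent_probe = sum(!present))
  chosen <- chosen[present, , drop = FALSE]
  out <- exprs[chosen$probe_id, , drop = FALSE]
  rownames(out) <- chosen$gene_id
  out
}

#' Array quality-control thresholds
#'
#' Thresholds for the standard microarray quality checks: background and
#' noise level, percentage of present calls, presence of bioB/C/D spike-in
#' controls, and the 3'/5' ratios of the housekeeping genes GAPDH and
#' ACTB (degraded RNA inflates the ratio). Defaults follow common
#' microarray practice (3'/5' ratio below 3, at least 25\% present calls,
#' spike-ins required) and are fully overridable.
#'
#' @param max_background maximal acceptable background intensity.
#' @param max_noise maximal acceptable noise (RawQ-style) level.
#' @param min_percent_present minimal percentage of present calls, in
#'   \[0, 100\].
#' @param max_35_ratio maximal 3'/5' ratio for GAPDH and ACTB.
#' @param require_bioBCD whether the bioB/C/D spike-ins must be detected.
#' @return named list of thresholds.
#' @export
qcThresholds <- function(max_background = 100, max_noise = 5,
                         min_percent_present = 25, max_35_ratio = 3,
                         require_bioBCD = TRUE) {
  for (v in c(max_background, max_noise, min_percent_present, max_35_ratio))
    assertNumericScalar(v, "threshold")
  if (min_percent_present < 0 || min_percent_present > 100)
    stopf("'min_percent_present' must be in [0, 100]")
  list(max_background = max_background, max_noise = max_noise,
       min_percent_present = min_percent_present,
       max_35_ratio = max_35_ratio,
       require_bioBCD = isTRUE(require_bioBCD))
}

#' Flag arrays by quality-control metrics
#'
#' Classifies each array as \code{"pass"}, \code{"fail"} or
#' \code{"unevaluable"}: \code{fail} iff any non-missing metric violates
#' its threshold (reasons list every violated check); \code{unevaluable}
#' iff nothing violates but at least one required metric is missing.
#' Loosening every threshold can never turn a pass into a fail.
#'
#' @param metrics data.frame with columns \code{sample_id} and any of
#'   \code{background}, \code{noise}, \code{percent_present},
#'   \code{bioBCD_ok}, \code{gapdh_35_ratio}, \code{actb_35_ratio};
#'   missing values allowed.
#' @param thresholds as from [qcThresholds()].
#' @return data.frame with columns \code{sample_id}, \code{status},
#'   \code{reasons} (comma-separated violated checks, \code{""} if none).
#' @export
qcFlag <- function(metrics, thresholds = qcThresholds()) {
  if (!"sample_id" %in% colnames(metrics))
    stopf("'metrics' needs a sample_id column")
  if (anyDuplicated(metrics$sample_id)) stopf("duplicated sample ids in metrics")
  get <- function(col) if (col %in% colnames(metrics)) metrics[[col]] else
    rep(NA, nrow(metrics))
  checks <- list(
    background      = get("background")      >  thresholds$max_background,
    noise           = get("noise")           >  thresholds$max_noise,
    percent_present = get("percent_present") <  thresholds$min_percent_present,
    gapdh_35_ratio  = get("gapdh_35_ratio")  >  thresholds$max_35_ratio,
    actb_35_ratio   = get("actb_35_ratio")   >  thresholds$max_35_ratio)
  required_null <- Reduce(`|`, lapply(checks, is.na))
  if (thresholds$require_bioBCD) {
    bio <- get("bioBCD_ok")
    checks$bioBCD <- !is.na(bio) & !as.logical(bio)
    required_null <- required_null | is.na(bio)
  }
  reasons <- character(nrow(metrics))
  status <- character(nrow(metrics))
  for (i in seq_len(nrow(metrics))) {
    vi <- names(checks)[vapply(checks, function(ch) isTRUE(ch[i]), logical(1))]
    reasons[i] <- paste(vi, collapse = ",")
    status[i] <- if (length(vi)) "fail"
    else if (isTRUE(required_null[i])) "unevaluable"
    else "pass"
  }
  data.frame(sample_id = metrics$sample_id, status = status,
             reasons = reasons, stringsAsFactors = FALSE)
}
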