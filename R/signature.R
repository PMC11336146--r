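## Signature construction: directional per-gene Cox screen and
## sign-weighted mean scoring.

#' Directional per-gene Cox screen
#'
#' Investigates each gene individually for its impact on relapse-free
#' survival with a univariate Cox model on the (optionally per-gene
#' standardized) continuous expression, and assigns the gene a weight from
#' the direction of its hazard ratio: +1 when HR > 1 (higher expression,
#' worse outcome), -1 when 0 < HR < 1, and 0 — excluded from the
#' signature — when the gene is constant or the fit does not converge.
#' The sign of the coefficient is invariant to standardization and to any
#' positive affine transform of a gene's expression.
#'
#' @param cohort a \code{SurvCohort}, or a genes x samples matrix (then
#'   \code{time}/\code{event} must be given).
#' @param genes optional subset of gene ids to screen (e.g. a senescence
#'   gene list); default: all genes in the cohort. Requested genes absent
#'   from the matrix are dropped with a logged count.
#' @param time,event survival outcome when \code{cohort} is a bare matrix.
#' @param standardize fit on per-gene standardized expression
#'   (recommended; hazard ratios are then per standard deviation).
#' @param medianSplit screen on the median-dichotomized gene instead of
#'   the continuous value.
#' @return a \linkS4class{GeneWeights} object.
#' @export
screenGenes <- function(cohort, genes = NULL, time = NULL, event = NULL,
                        standardize = TRUE, medianSplit = FALSE) {
  if (is(cohort, "SurvCohort")) {
    expr <- assay(cohort, "exprs")
    time <- colData(cohort)$time
    event <- colData(cohort)$event
  } else {
    expr <- cohort
    if (is.null(time) || is.null(event))
      stopf("'time' and 'event' are required with a bare matrix")
  }
  if (ncol(expr) != length(time))
    stopf("expression samples (%d) do not align with survival records (%d)",
          ncol(expr), length(time))
  checkSurv(time, event, min_events = 1L)
  if (!is.null(genes)) {
    absent <- setdiff(genes, rownames(expr))
    if (length(absent) == length(genes)) stopf("none of the requested genes are present")
    if (length(absent)) logMsg("screen_genes", genes_absent = length(absent))
    expr <- expr[intersect(genes, rownames(expr)), , drop = FALSE]
  }
  n_genes <- nrow(expr)
  hr <- ci_low <- ci_high <- p <- rep(NA_real_, n_genes)
  weight <- integer(n_genes)
  reason <- rep(NA_character_, n_genes)
  for (i in seq_len(n_genes)) {
    x <- expr[i, ]
    if (sd(x) == 0) {
      reason[i] <- "constant"
      next
    }
    if (medianSplit) {
      x <- as.numeric(x > median(x))
      if (sd(x) == 0) { reason[i] <- "constant"; next }
    } else if (standardize) {
      x <- (x - mean(x)) / sd(x)
    }
    fit <- tryCatch(coxFit(x, time, event), error = function(e) NULL)
    if (is.null(fit)) { reason[i] <- "fit_error"; next }
    if (!fit$converged) { reason[i] <- "nonconvergence"; next }
    hr[i] <- fit$hr; ci_low[i] <- fit$ci_low; ci_high[i] <- fit$ci_high
    p[i] <- fit$p
    weight[i] <- if (fit$hr > 1) 1L else if (fit$hr < 1) -1L else 0L
    if (fit$hr == 1) reason[i] <- "hr_equal_one"
  }
  n_dropped <- sum(weight == 0L)
  if (n_dropped) logMsg("screen_genes", genes_weight_zero = n_dropped)
  new("GeneWeights", table = DataFrame(
    gene_id = rownames(expr), hr = hr, ci_low = ci_low, ci_high = ci_high,
    p = p, weight = weight, source = "fitted", reason = reason))
}

#' Sign-weighted mean signature score
#'
#' The signature score of a sample is the average weighted expression over
#' signature genes: \code{mean over genes g with weight != 0 of
#' weight(g) * exprs[g, s]}. Genes present in the weight table but absent
#' from the matrix are skipped with a logged count; a signature with zero
#' usable genes is an error.
#'
#' @param cohort a \code{SurvCohort} or a genes x samples matrix.
#' @param weights a \linkS4class{GeneWeights}.
#' @return named numeric vector of per-sample scores.
#' @examples
#' expr <- matrix(c(800, 200), nrow = 2,
#'                dimnames = list(c("gA", "gB"), "s1"))
#' w <- fixedSignature(data.frame(gene_id = c("gA", "gB"),
#'                                fixed_weight = c(1, -1)))
#' scoreSamples(cbind(expr, s2 = c(100, 100)), w)  # s1: (800-200)/2 = 300
#' @export
scoreSamples <- function(cohort, weights) {
  stopifnot(is(weights, "GeneWeights"))
  expr <- if (is(cohort, "SurvCohort")) assay(cohort, "exprs") else cohort
  tb <- weightTable(weights)
  tb <- tb[tb$weight != 0, , drop = FALSE]
  if (!nrow(tb)) stopf("signature has no genes with nonzero weight")
  absent <- setdiff(tb$gene_id, rownames(expr))
  if (length(absent)) logMsg("score_samples", genes_skipped_absent = length(absent))
  tb <- tb[tb$gene_id %in% rownames(expr), , drop = FALSE]
  if (!nrow(tb)) stopf("no signature gene is present in the expression matrix")
  w <- setNames(tb$weight, tb$gene_id)
  colMeans(expr[tb$gene_id, , drop = FALSE] * w)
}

#' Build a signature from a fixed gene list
#'
#' Turns a gene list with pre-fixed +/-1 weights (e.g. a published
#' signature supplement) into a \linkS4class{GeneWeights} with
#' \code{source = "fixed"}; hazard ratios and p-values are \code{NA}.
#'
#' @param entries data.frame as from [readGeneList()]; every row must have
#'   \code{fixed_weight} of -1 or +1.
#' @return a \linkS4class{GeneWeights}.
#' @export
fixedSignature <- function(entries) {
  if (!all(c("gene_id", "fixed_weight") %in% colnames(entries)))
    stopf("'entries' needs columns gene_id and fixed_weight")
  if (anyDuplicated(entries$gene_id))
    stopf("duplicated gene id(s): %s",
          paste(unique(entries$gene_id[duplicated(entries$gene_id)]), collapse = ", "))
  w <- entries$fixed_weight
  if (anyNA(w)) stopf("missing fixed weight for gene '%s'",
                      entries$gene_id[which(is.na(w))[1]])
  if (!all(w %in% c(-1, 1)))
    stopf("fixed weights must be -1 or +1 (gene '%s')",
          entries$gene_id[which(!w %in% c(-1, 1))[1]])
  new("GeneWeights", table = DataFrame(
    gene_id = entries$gene_id, hr = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_, p = NA_real_, weight = as.integer(w),
    source = "fixed", reason = NA_character_))
}

#' Serialize a GeneWeights table to TSV
#' @param weights a \linkS4class{GeneWeights}.
#' @param path output path.
#' @export
writeGeneWeights <- function(weights, path) {
  stopifnot(is(weights, "GeneWeights"))
  tb <- weightTable(weights)
  num <- vapply(tb, is.numeric, logical(1))
  tb[num] <- lapply(tb[num], function(x) ifelse(is.na(x), NA,
    format(x, digits = 10, trim = TRUE)))
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
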