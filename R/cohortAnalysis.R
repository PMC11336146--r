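## Whole-cohort analysis, per-dataset replication and paired bivariate
## Cox models against clinical covariates.

#' Full single-cohort signature analysis
#'
#' Scores the cohort with the given weights, scans cutoffs between the
#' score quartiles, dichotomizes at the selected cutoff and derives the
#' Kaplan-Meier curves and the high-vs-low Cox fit — the complete
#' univariate analysis for one cohort.
#'
#' @param cohort a \code{SurvCohort}.
#' @param weights a \linkS4class{GeneWeights}; when \code{NULL}, weights
#'   are first fitted on this cohort with [screenGenes()].
#' @param genes optional gene subset for screening (ignored when
#'   \code{weights} given).
#' @param ... passed to [scanCutoffs()].
#' @return list with \code{weights}, \code{scores}, \code{scan}
#'   (\linkS4class{CutoffScan}), \code{groups} (logical, TRUE = high
#'   score), \code{cox} (high vs low), \code{logrank}, \code{km}
#'   (list of low/high curves).
#' @export
analyzeCohort <- function(cohort, weights = NULL, genes = NULL, ...) {
  stopifnot(is(cohort, "SurvCohort"))
  if (is.null(weights)) weights <- screenGenes(cohort, genes = genes)
  scores <- scoreSamples(cohort, weights)
  cd <- colData(cohort)
  scan <- scanCutoffs(scores, cd$time, cd$event, ...)
  sel <- selectedCutoff(scan)
  hi <- scores > sel$cutoff
  cox <- coxFit(as.numeric(hi), cd$time, cd$event)
  lr <- logrankTest(hi, cd$time, cd$event)
  km <- list(low = kmEstimate(cd$time[!hi], cd$event[!hi]),
             high = kmEstimate(cd$time[hi], cd$event[hi]))
  list(weights = weights, scores = scores, scan = scan, groups = hi,
       cox = cox, logrank = lr, km = km)
}

#' Per-dataset replication of a signature
#'
#' Re-runs the scored analysis within each dataset of a multi-dataset
#' cohort using one shared weight table — so each run validates the same
#' signature — while the cutoff is re-optimized within the dataset
#' (optionally the whole-cohort cutoff is reused). Datasets with too few
#' samples or events are excluded and listed.
#'
#' @param cohort a multi-dataset \code{SurvCohort}.
#' @param weights shared \linkS4class{GeneWeights}.
#' @param minN minimal dataset size (default 30).
#' @param minEvents minimal number of events (default 10).
#' @param globalCutoff when non-\code{NULL}, dichotomize every dataset at
#'   this fixed cutoff instead of re-scanning.
#' @param ... passed to [scanCutoffs()].
#' @return data.frame with one row per retained dataset: \code{dataset_id},
#'   \code{n}, \code{events}, \code{cutoff}, \code{hr}, \code{ci_low},
#'   \code{ci_high}, \code{p}, \code{p_adj}, \code{direction_consistent}
#'   (HR > 1 for the high-score group). Excluded datasets and their
#'   reasons are in attribute \code{"excluded"}.
#' @export
perDataset <- function(cohort, weights, minN = 30L, minEvents = 10L,
                       globalCutoff = NULL, ...) {
  stopifnot(is(cohort, "SurvCohort"), is(weights, "GeneWeights"))
  cd <- colData(cohort)
  ids <- unique(cd$dataset_id)
  rows <- list(); excl <- list()
  for (d in ids) {
    sel <- cd$dataset_id == d
    n <- sum(sel); ev <- sum(cd$event[sel])
    if (n < minN || ev < minEvents) {
      excl[[d]] <- data.frame(dataset_id = d, n = n, events = ev,
                              reason = if (n < minN) "too_few_samples"
                                       else "too_few_events")
      next
    }
    sub <- cohort[, sel]
    scores <- scoreSamples(sub, weights)
    st <- cd$time[sel]; se <- cd$event[sel]
    res <- tryCatch({
      if (is.null(globalCutoff)) {
        scan <- scanCutoffs(scores, st, se, ...)
        s <- selectedCutoff(scan)
        list(cutoff = s$cutoff, p_adj = s$p_adj)
      } else list(cutoff = globalCutoff, p_adj = NA_real_)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[d]] <- data.frame(dataset_id = d, n = n, events = ev,
                              reason = "no_admissible_cutoff")
      next
    }
    hi <- scores > res$cutoff
    fit <- tryCatch(coxFit(as.numeric(hi), st, se), error = function(e) NULL)
    if (is.null(fit)) {
      excl[[d]] <- data.frame(dataset_id = d, n = n, events = ev,
                              reason = "degenerate_fit")
      next
    }
    rows[[d]] <- data.frame(dataset_id = d, n = n, events = ev,
                            cutoff = res$cutoff, hr = fit$hr,
                            ci_low = fit$ci_low, ci_high = fit$ci_high,
                            p = fit$p, p_adj = res$p_adj,
                            direction_consistent = fit$hr > 1)
  }
  if (!length(rows)) stopf("no dataset satisfies the sufficiency filter")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(dataset_id = character(), n = integer(), events = integer(),
               reason = character())
  rownames(excluded) <- NULL
  if (nrow(excluded)) logMsg("per_dataset", excluded = nrow(excluded))
  attr(out, "excluded") <- excluded
  out
}

#' Numeric encodings for clinical covariates
#'
#' The fixed encodings used by the paired models: \code{sex}
#' female = 0 / male = 1; \code{t_stage}, \code{n_stage}, \code{stage},
#' \code{grade} as ordinal integers; \code{m_stage} 0/1;
#' \code{location} proximal = 0 / distal = 1; \code{msi} ordinal with
#' stable = 0, high = 2 and the merged "stable or low" level at 0.5
#' (midpoint of stable and low).
#'
#' @param clin clinical data.frame.
#' @param covariate covariate column name.
#' @return numeric vector (NA where the covariate is missing).
#' @export
encodeCovariate <- function(clin, covariate) {
  if (!covariate %in% colnames(clin))
    stopf("covariate '%s' not present in the clinical table", covariate)
  v <- clin[[covariate]]
  maps <- list(
    sex      = c(female = 0, male = 1),
    m_stage  = c(`0` = 0, `1` = 1),
    location = c(proximal = 0, distal = 1),
    msi      = c(stable = 0, stable_or_low = 0.5, high = 2))
  if (covariate %in% names(maps)) {
    m <- maps[[covariate]]
    out <- unname(m[as.character(v)])
  } else {
    out <- suppressWarnings(as.numeric(as.character(v)))
    if (any(!is.na(v) & is.na(out)))
      stopf("covariate '%s' has non-ordinal level '%s'", covariate,
            v[which(!is.na(v) & is.na(out))[1]])
  }
  out
}

#' Paired bivariate Cox model: signature plus one covariate
#'
#' With heavy covariate missingness, a full multivariable model would
#' discard most samples; instead the signature is paired with one
#' clinical covariate at a time on that covariate's complete cases. The
#' signature enters dichotomized at the supplied cutoff (matching how its
#' univariate significance was established); both terms' hazard ratios
#' and p-values are reported from the same two-covariate fit.
#'
#' @param scores named signature scores.
#' @param clin clinical data.frame aligned with \code{scores} (same
#'   order), containing \code{time}, \code{event} and the covariate.
#' @param covariate covariate column name.
#' @param cutoff signature dichotomization cutoff (e.g. the whole-cohort
#'   selected cutoff).
#' @param continuous use the continuous score instead of dichotomizing.
#' @return list with \code{covariate_name}, \code{n_complete},
#'   \code{events}, \code{signature} and \code{covariate} (one-row
#'   data.frames as from [coxFit()]).
#' @export
pairedMultivariate <- function(scores, clin, covariate, cutoff,
                               continuous = FALSE) {
  if (length(scores) != nrow(clin))
    stopf("'scores' and 'clin' are not aligned")
  enc <- encodeCovariate(clin, covariate)
  keep <- !is.na(enc)
  if (!any(keep)) stopf("covariate '%s' is missing for every sample", covariate)
  sig <- if (continuous) scores[keep] else as.numeric(scores[keep] > cutoff)
  enc <- enc[keep]
  time <- clin$time[keep]; event <- clin$event[keep]
  checkSurv(time, event, min_events = 1L)
  if (length(unique(enc)) < 2L)
    stopf("covariate '%s' is constant on its complete cases", covariate)
  if (sd(sig) == 0)
    stopf("signature group is constant on the complete cases of '%s'", covariate)
  if (abs(stats::cor(sig, enc)) > 1 - 1e-10)
    stopf("signature and covariate '%s' are collinear on the complete cases",
          covariate)
  xm <- cbind(signature = sig, covariate = enc)
  fit <- coxFit(xm, time, event)
  list(covariate_name = covariate, n_complete = sum(keep),
       events = sum(event),
       signature = fit[fit$term == "signature", , drop = FALSE],
       covariate = fit[fit$term == "covariate", , drop = FALSE])
}

#' Run the paired model over every available covariate
#'
#' Loops [pairedMultivariate()] over the standard clinical covariates
#' present in the table, skipping (with a logged reason) covariates with
#' degenerate complete cases.
#'
#' @inheritParams pairedMultivariate
#' @param covariates covariate names to try.
#' @return data.frame with one row per fitted pair: \code{covariate},
#'   \code{n}, \code{events}, \code{hr_signature}, \code{p_signature},
#'   \code{hr_covariate}, \code{p_covariate}.
#' @export
pairedMultivariateAll <- function(scores, clin, cutoff,
                                  covariates = names(clinicalVocabulary()),
                                  continuous = FALSE) {
  covariates <- intersect(covariates, colnames(clin))
  rows <- list()
  for (cv in covariates) {
    res <- tryCatch(pairedMultivariate(scores, clin, cv, cutoff, continuous),
                    error = function(e) e)
    if (inherits(res, "error")) {
      logMsg("paired_multivariate", covariate = cv, skipped = "degenerate")
      next
    }
    rows[[cv]] <- data.frame(
      covariate = cv, n = res$n_complete, events = res$events,
      hr_signature = res$signature$hr, p_signature = res$signature$p,
      hr_covariate = res$covariate$hr, p_covariate = res$covariate$p)
  }
  if (!length(rows)) stopf("no covariate admitted a paired model")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
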