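## Survival primitives used by every downstream stage: Kaplan-Meier
## estimation, the two-group log-rank test and Cox proportional-hazards
## fitting. Fitting is delegated to the survival package (Efron tie
## handling); this layer fixes the contracts: validated inputs, a uniform
## result shape, Wald 95% intervals on the log-hazard scale, and flagged
## (never silent) non-convergence.

#' @importFrom survival Surv survfit coxph survdiff coxph.control
NULL

checkSurv <- function(time, event, min_n = 2L, min_events = 0L) {
  if (length(time) != length(event)) stopf("'time' and 'event' lengths differ")
  if (length(time) < min_n) stopf("at least %d subjects are required", min_n)
  if (any(!is.finite(time) | time <= 0)) stopf("'time' must be strictly positive")
  if (!all(event %in% c(0, 1))) stopf("'event' must be 0 or 1")
  if (sum(event) < min_events) stopf("at least %d event(s) required", min_events)
  invisible(TRUE)
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function S(t) nonparametrically: at each event
#' time the curve drops by the conditional fraction of at-risk subjects
#' with an event; censored subjects leave the risk set after their time.
#' With no censoring the estimate equals one minus the empirical CDF of
#' the event times. Confidence bands use Greenwood's variance on the
#' log scale (the survfit default).
#'
#' @param time positive follow-up times (months).
#' @param event 0/1 event indicators.
#' @param conf include 95\% Greenwood confidence bands.
#' @return data.frame with one row per event time: \code{time},
#'   \code{n_risk}, \code{n_event}, \code{survival} and, when requested,
#'   \code{lower}/\code{upper}.
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 0, 1))
#' @export
kmEstimate <- function(time, event, conf = TRUE) {
  checkSurv(time, event, min_n = 1L)
  fit <- survfit(Surv(time, event) ~ 1, conf.type = if (conf) "log" else "none")
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep], survival = fit$surv[keep])
  if (conf) {
    out$lower <- fit$lower[keep]
    out$upper <- fit$upper[keep]
  }
  out
}

#' Two-group log-rank test
#'
#' The standard 1-df log-rank comparison: at each event time the observed
#' events per group are compared with those expected under a common
#' hazard, accumulated over risk sets, and referred to a chi-square
#' distribution.
#'
#' @param group two-level grouping (factor, character or 0/1).
#' @param time,event survival outcome as in [kmEstimate()].
#' @return list with \code{chi_square}, \code{p} and \code{df}.
#' @export
logrankTest <- function(group, time, event) {
  checkSurv(time, event, min_events = 1L)
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2L)
    stopf("'group' must have exactly 2 non-empty levels")
  sd <- survdiff(Surv(time, event) ~ g)
  chisq <- unname(sd$chisq)
  list(chi_square = chisq, p = pchisq(chisq, df = 1L, lower.tail = FALSE),
       df = 1L)
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model by maximizing the partial likelihood with Efron tie
#' handling, for one or two numeric covariates. Each term is reported with
#' its log-hazard coefficient, hazard ratio, Wald 95\% confidence interval
#' (\code{exp(beta +/- 1.96 se)}) and two-sided Wald p-value. A constant
#' covariate is an error; non-convergence (e.g. monotone likelihood under
#' perfect separation) yields a flagged result (\code{converged = FALSE}),
#' not a crash.
#'
#' @param x numeric vector, or matrix/data.frame with 1-2 numeric columns.
#' @param time,event survival outcome; at least one event.
#' @return data.frame with one row per covariate: \code{term},
#'   \code{beta}, \code{se}, \code{hr}, \code{ci_low}, \code{ci_high},
#'   \code{p}, \code{n}, \code{events}, \code{converged}.
#' @examples
#' set.seed(1)
#' grp <- rep(0:1, each = 100)
#' tt <- rexp(200, rate = 0.01 * exp(log(2) * grp))
#' coxFit(grp, tt, rep(1, 200))
#' @export
coxFit <- function(x, time, event) {
  xm <- as.matrix(x)
  if (!is.numeric(xm)) stopf("covariates must be numeric")
  if (ncol(xm) > 2L) stopf("at most 2 covariates are supported")
  if (is.null(colnames(xm)))
    colnames(xm) <- if (ncol(xm) == 1L) "x" else paste0("x", seq_len(ncol(xm)))
  checkSurv(time, event, min_events = 1L)
  if (nrow(xm) != length(time)) stopf("covariate and outcome lengths differ")
  if (any(!is.finite(xm))) stopf("covariates must be finite")
  csd <- apply(xm, 2L, sd)
  if (any(csd == 0))
    stopf("constant covariate: %s", paste(colnames(xm)[csd == 0], collapse = ", "))
  converged <- TRUE
  fit <- withCallingHandlers(
    coxph(Surv(time, event) ~ xm, ties = "efron",
          control = coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit))
  se <- sqrt(diag(fit$var))
  data.frame(term = colnames(xm), beta = beta, se = se, hr = exp(beta),
             ci_low = exp(beta - .z95 * se), ci_high = exp(beta + .z95 * se),
             p = 2 * stats::pnorm(-abs(beta / se)),
             n = fit$n, events = fit$nevent, converged = converged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Format a p-value in the 2-significant-digit scientific style
#' used throughout the package's reports (e.g. \code{"6.4e-16"}).
#' @param p p-value(s).
#' @return character vector.
#' @export
formatP <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi >= 0.001) sprintf("%.2g", pi) else sprintf("%.1e", pi)
  }, character(1))
}
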