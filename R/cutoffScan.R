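## Exhaustive dichotomization of the signature score between the score
## quartiles, with false-discovery-rate correction over the scanned family.

#' Scan all cutoffs between the score quartiles
#'
#' Rather than committing to one dichotomization point, every unique
#' observed score value v with Q1 <= v < Q3 is tried as a cutoff
#' (low group: score <= v; high group: score > v — the test statistic only
#' changes at observed values, so this is exhaustive). Each admissible
#' cutoff yields a hazard ratio of the high- over the low-score group and
#' a p-value; p-values are Benjamini-Hochberg adjusted across the scanned
#' family, correcting the optimism of selecting the minimum. The selected
#' cutoff minimizes the raw p-value, ties broken toward the cutoff nearest
#' the median score.
#'
#' @param scores named numeric signature scores (at least 4 distinct
#'   values).
#' @param time,event survival outcome aligned with \code{scores}; at
#'   least one event.
#' @param qLow,qHigh scan bounds as score quantiles (type-7,
#'   linear-interpolation convention), defaults the lower and upper
#'   quartile.
#' @param minGroup minimal group size at an admissible cutoff; default
#'   10\% of n with a floor of 5.
#' @param test per-cutoff test: \code{"cox"} (Wald p from the
#'   dichotomized Cox fit; default, since a hazard ratio is reported per
#'   cutoff) or \code{"logrank"}.
#' @param quantileType quantile convention passed to
#'   \code{stats::quantile}.
#' @return a \linkS4class{CutoffScan}.
#' @export
scanCutoffs <- function(scores, time, event, qLow = 0.25, qHigh = 0.75,
                        minGroup = NULL, test = c("cox", "logrank"),
                        quantileType = 7L) {
  test <- match.arg(test)
  n <- length(scores)
  if (n != length(time)) stopf("'scores' and outcome lengths differ")
  checkSurv(time, event, min_n = 4L, min_events = 1L)
  if (length(unique(scores)) < 4L)
    stopf("at least 4 distinct score values are required")
  if (!(qLow < qHigh) || qLow < 0 || qHigh > 1)
    stopf("invalid quantile bounds")
  if (is.null(minGroup)) minGroup <- max(5L, floor(0.1 * n))
  qq <- quantile(scores, c(qLow, qHigh), type = quantileType, names = FALSE)
  cand <- sort(unique(scores))
  cand <- cand[cand >= qq[1] & cand < qq[2]]
  if (!length(cand)) stopf("no candidate cutoff between the quartiles")
  rows <- lapply(cand, function(v) {
    hi <- scores > v
    n_low <- sum(!hi); n_high <- sum(hi)
    if (n_low < minGroup || n_high < minGroup) return(NULL)
    if (sum(event[hi]) + sum(event[!hi]) < 1L) return(NULL)
    res <- tryCatch({
      if (test == "cox") {
        fit <- coxFit(as.numeric(hi), time, event)
        c(hr = fit$hr, p = fit$p)
      } else {
        fit <- coxFit(as.numeric(hi), time, event)
        lr <- logrankTest(hi, time, event)
        c(hr = fit$hr, p = lr$p)
      }
    }, error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(cutoff = v, hr = res[["hr"]], p = res[["p"]],
               n_low = n_low, n_high = n_high)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab))
    stopf("no admissible cutoff (all candidates give a group below %d)", minGroup)
  tab$p_adj <- fdrAdjust(tab$p)
  med <- median(scores)
  best <- which(tab$p == min(tab$p))
  if (length(best) > 1L) best <- best[which.min(abs(tab$cutoff[best] - med))]
  sel <- list(cutoff = tab$cutoff[best], hr = tab$hr[best], p = tab$p[best],
              p_adj = tab$p_adj[best], hr_range = range(tab$hr),
              n_low = tab$n_low[best], n_high = tab$n_high[best])
  new("CutoffScan",
      table = DataFrame(tab[c("cutoff", "hr", "p", "p_adj", "n_low", "n_high")]),
      selected = sel, scores = scores)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' The step-up procedure: sorted p-values are multiplied by m/rank,
#' monotonicity is enforced from the largest rank down and values are
#' capped at 1; results are returned in input order. Adjusted values are
#' never below the raw ones and preserve the ordering of the input.
#'
#' @param p p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdrAdjust <- function(p) {
  if (!length(p)) stopf("'p' is empty")
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stopf("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Significance-vs-cutoff profile
#'
#' Flattens a scan into the table behind the significance-versus-cutoff
#' plot: one row per scanned cutoff with -log10(p) and the hazard ratio,
#' and exactly one row flagged as the selected (minimum-p) cutoff.
#'
#' @param scan a \linkS4class{CutoffScan}.
#' @return data.frame with columns \code{cutoff}, \code{neg_log10_p},
#'   \code{hr}, \code{selected}.
#' @export
scanProfile <- function(scan) {
  stopifnot(is(scan, "CutoffScan"))
  tab <- scanTable(scan)
  sel <- selectedCutoff(scan)
  data.frame(cutoff = tab$cutoff, neg_log10_p = -log10(tab$p), hr = tab$hr,
             selected = tab$cutoff == sel$cutoff)
}

#' Plot the significance-vs-cutoff profile
#'
#' Draws -log10(p) against the scanned cutoff with the selected
#' (minimum-p) cutoff circled in red, and the per-cutoff hazard ratio on
#' a secondary panel.
#'
#' @param scan a \linkS4class{CutoffScan}.
#' @param path output file (.svg or .png); when \code{NULL}, draws on the
#'   current device.
#' @return the profile table, invisibly.
#' @export
plotScanProfile <- function(scan, path = NULL) {
  prof <- scanProfile(scan)
  if (!is.null(path)) {
    openDevice(path, width = 7, height = 6)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  plot(prof$cutoff, prof$neg_log10_p, type = "l", xlab = "cutoff",
       ylab = expression(-log[10](p)), main = "Significance vs cutoff")
  sel <- prof[prof$selected, ]
  graphics::points(sel$cutoff, sel$neg_log10_p, col = "red", cex = 2, lwd = 2)
  plot(prof$cutoff, prof$hr, type = "l", xlab = "cutoff", ylab = "HR")
  graphics::abline(h = 1, lty = 2, col = "grey")
  invisible(prof)
}
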