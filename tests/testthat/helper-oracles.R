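## Independent oracles used to cross-check the survival machinery. These
## deliberately share no code with the package: the product-limit curve is
## multiplied out by hand, the log-rank statistic accumulates the O-E/V
## table risk set by risk set, and the Cox coefficient is the argmax of
## the explicitly enumerated partial likelihood on a parameter grid.

## Product-limit estimate by direct accumulation (events precede
## censorings at tied times, the same convention the package uses).
handKM <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  etimes <- sort(unique(time[event == 1]))
  surv <- numeric(length(etimes))
  s <- 1
  for (k in seq_along(etimes)) {
    t <- etimes[k]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = etimes, survival = surv)
}

## Two-group log-rank chi-square via the hypergeometric O-E/V sums.
bruteLogrank <- function(group, time, event) {
  g <- as.integer(as.factor(group)) - 1L
  etimes <- sort(unique(time[event == 1]))
  OE <- 0; V <- 0
  for (t in etimes) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    OE <- OE + d1 - d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- OE^2 / V
  list(chi_square = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

## Cox log-partial-likelihood on a beta grid (valid for untied event
## times); returns the grid argmax.
gridCoxBeta <- function(x, time, event, lo = -4, hi = 4, step = 1e-4) {
  stopifnot(!anyDuplicated(time[event == 1]))
  B <- seq(lo, hi, by = step)
  ll <- numeric(length(B))
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + B * x[i] - log(colSums(exp(outer(x[risk], B))))
  }
  B[which.max(ll)]
}

## Benjamini-Hochberg step-up by its textbook definition.
handBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## Small two-group exponential survival fixture.
simTwoGroup <- function(n, hr = 2, rate0 = 0.05, censor_at = Inf) {
  grp <- rep(0:1, length.out = n)
  tt <- rexp(n, rate0 * hr^grp)
  event <- as.numeric(tt <= censor_at)
  list(group = grp, time = pmin(tt, censor_at), event = event)
}
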