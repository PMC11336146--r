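## Internal helpers shared across modules.

#' @importFrom stats quantile median setNames sd pchisq qnorm rbinom rnorm
#'   runif rexp p.adjust complete.cases coef pnorm
#' @importFrom utils read.delim write.table head
NULL

## Round half away from zero, the convention used for printed clinical
## percentage tables (base round() rounds half to even).
roundHalfAway <- function(x, digits = 2L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## Tokens treated as missing in clinical/categorical columns. Anything else
## outside the declared vocabulary is an error, never silently nulled.
.na_tokens <- c("", "na", "nan")

isMissingToken <- function(x) {
  is.na(x) | tolower(trimws(as.character(x))) %in% .na_tokens
}

## Stage-tagged key=value log line; suppressible like any message().
logMsg <- function(stage, ...) {
  kv <- c(...)
  body <- if (length(kv)) paste(names(kv), unname(kv), sep = "=", collapse = " ") else ""
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, body))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

## Wald two-sided p from beta/se; z constant matching 95% CI presentation.
.z95 <- 1.959964

assertNumericScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  invisible(x)
}
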