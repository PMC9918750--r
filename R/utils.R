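# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emit a structured log message
#'
#' Logging is routed through `message()` so callers can silence it with
#' `suppressMessages()` or `options(siascore.verbose = FALSE)`.
#' @param fmt `sprintf` format string.
#' @param ... values interpolated into `fmt`.
#' @keywords internal
sia_log <- function(fmt, ...) {
  if (isTRUE(getOption("siascore.verbose", TRUE))) {
    message(sprintf(paste0("[siascore] ", fmt), ...))
  }
  invisible(NULL)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Cumulative trapezoidal integral, same length as x, starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# Rank-statistic AUC of a score against a binary outcome (1 = case).
# Ties in the score contribute 1/2, as in the Mann-Whitney statistic.
auc_rank <- function(score, outcome) {
  outcome <- as.integer(outcome)
  n1 <- sum(outcome == 1L)
  n0 <- sum(outcome == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: outcome has a single class", call. = FALSE)
  }
  r <- rank(score)
  (sum(r[outcome == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Numeric columns formatted so that write -> read round trips are exact.
format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

stop_missing_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(NULL)
}
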