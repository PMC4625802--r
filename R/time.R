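#' Time intervals and year fractions
#'
#' Utility observations enter the model attached to a follow-up interval
#' (so many days, weeks or months after treatment). QALYs weight a utility
#' by the fraction of a year that interval represents. The conventions are
#' the ones the model's printed QALYs imply: a 364-day year for day-based
#' intervals (52 weeks of 7 days), 52 weeks per year, 12 months per year.
#'
#' @param value positive duration.
#' @param unit one of `"days"`, `"weeks"`, `"months"`.
#' @return `time_interval()` returns an object of class `"time_interval"`;
#'   `year_fraction()` returns the interval expressed as a fraction of a
#'   year.
#' @examples
#' year_fraction(time_interval(3, "months"))  # 0.25
#' year_fraction(time_interval(7, "days"))    # 7/364
#' @export
time_interval <- function(value, unit = c("days", "weeks", "months")) {
  unit <- match.arg(unit)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0) {
    stop("interval value must be a single positive number", call. = FALSE)
  }
  structure(list(value = as.numeric(value), unit = unit),
            class = "time_interval")
}

#' @rdname time_interval
#' @param x a `time_interval` (or a list with `value` and `unit` fields).
#' @export
year_fraction <- function(x) {
  if (!inherits(x, "time_interval")) {
    if (is.list(x) && !is.null(x$value) && !is.null(x$unit)) {
      x <- time_interval(x$value, x$unit)
    } else {
      stop("'x' must be a time_interval", call. = FALSE)
    }
  }
  denom <- c(days = 364, weeks = 52, months = 12)[[x$unit]]
  x$value / denom
}

#' @export
print.time_interval <- function(x, ...) {
  cat(sprintf("<time_interval> %g %s (%.6f year)\n",
              x$value, x$unit, year_fraction(x)))
  invisible(x)
}

#' @export
format.time_interval <- function(x, ...) sprintf("%g %s", x$value, x$unit)
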