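#' Total cost including productivity loss
#'
#' Adds the indirect cost of sick leave to a procedure's direct cost:
#' `direct_cost + trw_days * daily_rate`, where `trw_days` is the time to
#' return to work and `daily_rate` the productivity value of one working
#' day. The default rate of EUR 285/day is the one the model's published
#' total-cost rows reconstruct to the cent; it can be overridden here or
#' in the parameter file.
#'
#' @param direct_cost direct procedure cost (EUR), nonnegative.
#' @param trw_days days to return to work, nonnegative.
#' @param daily_rate productivity cost per day off work (EUR), nonnegative.
#' @return total cost in EUR.
#' @examples
#' total_cost(1390.66, 4, 285)   # 2530.66
#' total_cost(924.00, 17, 285)   # 5769.00
#' @export
total_cost <- function(direct_cost, trw_days, daily_rate = 285) {
  args <- c(direct_cost = direct_cost, trw_days = trw_days,
            daily_rate = daily_rate)
  if (!is.numeric(args) || any(!is.finite(args))) {
    stop("all cost arguments must be finite numbers", call. = FALSE)
  }
  if (any(args < 0)) {
    stop("cost arguments must be nonnegative", call. = FALSE)
  }
  direct_cost + trw_days * daily_rate
}
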