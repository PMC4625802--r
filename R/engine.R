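#' Incremental cost and effect
#'
#' Differences are taken as EVLT minus HL/S throughout the package: a
#' positive incremental cost means EVLT is the more expensive strategy,
#' a positive incremental effect means EVLT yields more QALYs.
#'
#' @param outcomes a [scenario_outcomes()] object, or a list with `evlt`
#'   and `hls` entries each holding `cost` and `qaly`.
#' @return named numeric vector `c(delta_cost, delta_effect)`.
#' @examples
#' p <- cea_parameters()
#' incremental(scenario_outcomes(p, "base2"))
#' @export
incremental <- function(outcomes) {
  c(delta_cost = outcomes$evlt$cost - outcomes$hls$cost,
    delta_effect = outcomes$evlt$qaly - outcomes$hls$qaly)
}

#' Incremental cost-effectiveness ratio
#'
#' The ratio of incremental cost to incremental effect. The ICER is only
#' a decision-relevant quantity in the trade-off quadrants; when one
#' strategy dominates (deltas of the quadrant signs NW or SE) or the
#' effect difference is zero, the ratio is returned as `NA` with a
#' `reason` attribute (`"dominance"` or `"zero effect"`) rather than an
#' error. Following the source analysis, scenarios where both arms have
#' negative QALYs still report the plain ratio of deltas.
#'
#' @param delta_cost incremental cost (EUR).
#' @param delta_effect incremental effect (QALY).
#' @return EUR per QALY, or `NA` with a `reason` attribute.
#' @examples
#' icer(303.97, 0.025)   # 12158.8
#' icer(466.66, 0)       # NA, reason "zero effect"
#' @export
icer <- function(delta_cost, delta_effect) {
  if (delta_effect == 0) {
    return(structure(NA_real_, reason = "zero effect"))
  }
  if (sign(delta_cost) != sign(delta_effect) &&
      delta_cost != 0) {
    # NW (costlier, less effective) or SE (cheaper, more effective):
    # one strategy dominates, no meaningful ratio
    return(structure(NA_real_, reason = "dominance"))
  }
  delta_cost / delta_effect
}

#' Dominance classification
#'
#' Weak dominance: a strategy is dominated when the rival is no worse on
#' both cost and effect and strictly better on at least one. Equal cost
#' and equal effect is a trade-off (neither dominated). The weak rule is
#' what the model requires — several scenarios have exactly equal QALYs
#' and differ only in cost, and are classified as dominated.
#'
#' @inheritParams incremental
#' @return one of `"EVLT_dominated"`, `"HLS_dominated"`, `"tradeoff"`.
#' @export
classify_dominance <- function(outcomes) {
  dc <- outcomes$evlt$cost - outcomes$hls$cost
  de <- outcomes$evlt$qaly - outcomes$hls$qaly
  if (dc >= 0 && de <= 0 && (dc > 0 || de < 0)) return("EVLT_dominated")
  if (dc <= 0 && de >= 0 && (dc < 0 || de > 0)) return("HLS_dominated")
  "tradeoff"
}

#' Net monetary benefit
#'
#' `wtp * QALY - cost`: converts a strategy's outcome to a single money
#' scale at a given willingness to pay per QALY. The strategy with the
#' higher NMB is optimal at that threshold.
#'
#' @param cost expected cost (EUR).
#' @param effect expected QALYs.
#' @param wtp willingness to pay (EUR/QALY), nonnegative.
#' @return NMB in EUR.
#' @examples
#' nmb(1363.55, 0.171, 50000)  # 7186.45
#' @export
nmb <- function(cost, effect, wtp) {
  if (any(wtp < 0)) stop("'wtp' must be nonnegative", call. = FALSE)
  wtp * effect - cost
}

#' Optimal strategy at a willingness-to-pay threshold
#'
#' Compares net monetary benefit of the two strategies; ties retain the
#' conventional comparator HL/S.
#'
#' @inheritParams incremental
#' @param wtp willingness to pay (EUR/QALY).
#' @return `"EVLT"` or `"HLS"`.
#' @export
optimal_at_wtp <- function(outcomes, wtp) {
  d <- nmb(outcomes$evlt$cost, outcomes$evlt$qaly, wtp) -
       nmb(outcomes$hls$cost, outcomes$hls$qaly, wtp)
  if (d > 0) "EVLT" else "HLS"
}
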