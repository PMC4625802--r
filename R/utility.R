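#' SF-36 domain profile
#'
#' Bundles the eight SF-36 domain scores (Physical Functioning, Role
#' Physical, Bodily Pain, General Health, Vitality, Social Functioning,
#' Role Emotional, Mental Health), each on the 0 (worst) to 100 (best)
#' scale, for use with [hui2_from_sf36()].
#'
#' @param PF,RP,BP,GH,VT,SF,RE,MH domain scores in \[0, 100\].
#' @return a named numeric vector of class `"sf36_profile"`.
#' @export
sf36_profile <- function(PF, RP, BP, GH, VT, SF, RE, MH) {
  p <- c(PF = PF, RP = RP, BP = BP, GH = GH, VT = VT, SF = SF,
         RE = RE, MH = MH)
  if (!is.numeric(p) || length(p) != 8L || anyNA(p)) {
    stop("all eight SF-36 domain scores are required", call. = FALSE)
  }
  if (any(p < 0 | p > 100)) {
    stop("SF-36 domain scores must lie in [0, 100]", call. = FALSE)
  }
  structure(as.numeric(p), names = names(p), class = "sf36_profile")
}

sf36_domains <- c("PF", "RP", "BP", "GH", "VT", "SF", "RE", "MH")

#' Impute a HUI2 utility score from an SF-36 profile
#'
#' Linear mapping `intercept + sum(slope_d * score_d)` over the eight
#' SF-36 domains, following the published regression approach for imputing
#' Health Utilities Index Mark II scores when no direct utility elicitation
#' is available. The mapping coefficients are injected (coefficient sets
#' live in the parameter file); the result is deliberately not clamped to
#' \[0, 1\] — the registry's imputed scores exceed 1.
#'
#' @param profile an [sf36_profile()] or named numeric vector with the
#'   eight domain scores.
#' @param coeffs a list with `intercept` (scalar) and `slopes` (named
#'   numeric vector over the eight domains), optionally a `label`.
#' @return imputed utility score (unitless).
#' @examples
#' cf <- list(intercept = 0.9, slopes = setNames(numeric(8),
#'   c("PF","RP","BP","GH","VT","SF","RE","MH")))
#' hui2_from_sf36(sf36_profile(73, 50, 60, 70, 55, 80, 67, 75), cf)
#' @export
hui2_from_sf36 <- function(profile, coeffs) {
  p <- unclass(profile)
  if (!all(sf36_domains %in% names(p))) {
    stop("profile must carry all eight SF-36 domains", call. = FALSE)
  }
  p <- p[sf36_domains]
  if (any(!is.finite(p)) || any(p < 0 | p > 100)) {
    stop("SF-36 domain scores must lie in [0, 100]", call. = FALSE)
  }
  slopes <- unlist(coeffs$slopes)[sf36_domains]
  if (!is.finite(coeffs$intercept) || any(!is.finite(slopes))) {
    stop("mapping coefficients must be finite", call. = FALSE)
  }
  as.numeric(coeffs$intercept + sum(slopes * p))
}

#' Standard-gamble utility from a visual analogue scale rating
#'
#' Rescales a 0-100 mm VAS rating to \[0, 1\] and applies the conventional
#' power transformation `1 - (1 - v)^exponent` relating VAS values to
#' standard-gamble utilities. The default exponent 2.27 is the widely used
#' population-level estimate; `exponent = 1` reduces to the raw rescaled
#' VAS.
#'
#' @param vas VAS rating(s) in \[0, 100\].
#' @param exponent positive power-curve exponent.
#' @return SG utility in \[0, 1\], same length as `vas`.
#' @examples
#' sg_from_vas(50, exponent = 2)  # 0.75
#' @export
sg_from_vas <- function(vas, exponent = 2.27) {
  if (!is.numeric(vas) || any(!is.finite(vas)) ||
      any(vas < 0 | vas > 100)) {
    stop("'vas' must lie in [0, 100]", call. = FALSE)
  }
  if (!is.numeric(exponent) || length(exponent) != 1L || exponent <= 0) {
    stop("'exponent' must be a positive number", call. = FALSE)
  }
  1 - (1 - vas / 100)^exponent
}

#' Utility decrement from VAS pain
#'
#' Linear utility decrement for pain rated on a 0-100 mm VAS: each
#' additional millimetre lowers utility by `slope` (default 0.035, the
#' published regression estimate relating VAS pain to EQ-5D utility).
#' Returns a nonpositive decrement.
#'
#' @param vas_mm VAS pain in mm, in \[0, 100\].
#' @param slope decrement per mm (positive number).
#' @return utility decrement(s), `-slope * vas_mm`.
#' @examples
#' kovacs_disutility(8)   # -0.28
#' kovacs_disutility(11)  # -0.385
#' @export
kovacs_disutility <- function(vas_mm, slope = 0.035) {
  if (!is.numeric(vas_mm) || any(!is.finite(vas_mm)) ||
      any(vas_mm < 0 | vas_mm > 100)) {
    stop("'vas_mm' must lie in [0, 100]", call. = FALSE)
  }
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0) {
    stop("'slope' must be a positive number", call. = FALSE)
  }
  -slope * vas_mm
}

#' Interval-weighted QALY
#'
#' Converts a utility score (or decrement) observed over a follow-up
#' interval into quality-adjusted life years: `value * year_fraction(interval)`.
#' Sign is preserved, so decrements yield negative QALYs.
#'
#' @param value utility score or decrement (unitless).
#' @param interval a [time_interval()].
#' @return QALYs.
#' @examples
#' qaly(1.440, time_interval(3, "months"))   # 0.36
#' qaly(-0.28, time_interval(7, "days"))     # -0.0053846
#' @export
qaly <- function(value, interval) {
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop("'value' must be numeric and finite", call. = FALSE)
  }
  value * year_fraction(interval)
}
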