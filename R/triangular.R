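#' Triangular distribution specifications
#'
#' Parameter uncertainty in the probabilistic analysis is expressed with
#' three-point triangular distributions. `triangular()` builds an
#' explicit (min, mode, max) specification; the two constructors encode
#' the model's published rules for deriving a triangular from summary
#' statistics:
#'
#' * `triangular_from_quartiles()`: the span is obtained by doubling the
#'   distance from the mean to each quartile — `min = mean - 2(mean - q1)`,
#'   `mode = mean`, `max = mean + 2(q3 - mean)`.
#' * `triangular_from_sd()`: when only a point estimate is available, the
#'   standard deviation is assumed to be `sd_fraction` (default 0.5)
#'   times the absolute mean, and a symmetric triangular with that sd is
#'   used. A symmetric triangular of total width `w` has variance
#'   `w^2 / 24`, so the half-width is `sd * sqrt(6)`.
#'
#' @param min,mode,max triangular parameters, `min <= mode <= max`,
#'   `min < max`.
#' @param derivation provenance tag (`"explicit"`, `"from_quartiles"`,
#'   `"from_sd_halfmean"`).
#' @return an object of class `"triangular"` with fields `min`, `mode`,
#'   `max`, `derivation`.
#' @examples
#' triangular_from_quartiles(10, 8, 13)     # (6, 10, 16)
#' triangular_from_sd(100)                  # sd 50, half-width 50*sqrt(6)
#' @export
triangular <- function(min, mode, max, derivation = "explicit") {
  v <- c(min, mode, max)
  if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v))) {
    stop("triangular parameters must be finite numbers", call. = FALSE)
  }
  if (min > mode || mode > max) {
    stop("triangular parameters must satisfy min <= mode <= max",
         call. = FALSE)
  }
  if (min == max) {
    stop("zero-width triangular distribution (min == max)", call. = FALSE)
  }
  structure(list(min = min, mode = mode, max = max,
                 derivation = derivation), class = "triangular")
}

#' @rdname triangular
#' @param mean point estimate (becomes the mode).
#' @param q1,q3 lower and upper quartiles, `q1 <= mean <= q3`.
#' @export
triangular_from_quartiles <- function(mean, q1, q3) {
  if (q1 > mean || mean > q3) {
    stop("quartiles must satisfy q1 <= mean <= q3", call. = FALSE)
  }
  triangular(mean - 2 * (mean - q1), mean, mean + 2 * (q3 - mean),
             derivation = "from_quartiles")
}

#' @rdname triangular
#' @param sd_fraction assumed sd as a fraction of the absolute mean.
#' @export
triangular_from_sd <- function(mean, sd_fraction = 0.5) {
  if (mean == 0) {
    stop("mean of 0 gives no scale for the sd fallback", call. = FALSE)
  }
  if (sd_fraction <= 0) {
    stop("'sd_fraction' must be positive", call. = FALSE)
  }
  hw <- sd_fraction * abs(mean) * sqrt(6)
  triangular(mean - hw, mean, mean + hw, derivation = "from_sd_halfmean")
}

#' @rdname triangular
#' @param spec a `"triangular"` object.
#' @export
tri_mean <- function(spec) (spec$min + spec$mode + spec$max) / 3

#' @rdname triangular
#' @export
tri_var <- function(spec) {
  with(spec, (min^2 + mode^2 + max^2 - min * mode - min * max -
                mode * max) / 18)
}

#' @rdname triangular
#' @param n number of draws.
#' @export
rtriangular <- function(n, spec) {
  stopifnot(inherits(spec, "triangular"))
  u <- stats::runif(n)
  w <- spec$max - spec$min
  fc <- (spec$mode - spec$min) / w
  ifelse(u < fc,
         spec$min + sqrt(u * w * (spec$mode - spec$min)),
         spec$max - sqrt((1 - u) * w * (spec$max - spec$mode)))
}

#' @export
print.triangular <- function(x, ...) {
  cat(sprintf("<triangular> min %.4g, mode %.4g, max %.4g (%s); mean %.4g, sd %.4g\n",
              x$min, x$mode, x$max, x$derivation, tri_mean(x),
              sqrt(tri_var(x))))
  invisible(x)
}
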