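#' Probabilistic sensitivity analysis
#'
#' Monte Carlo recalculation of one scenario: each iteration draws both
#' strategies' cost and utility from triangular distributions, recomputes
#' the QALYs and the incremental cost/effect pair (EVLT minus HL/S), and
#' the cloud of pairs is summarized as cost-effectiveness-plane quadrant
#' fractions, the probability that EVLT is cost-effective at the
#' threshold, and the full acceptability curve.
#'
#' Distributions default to the model's fallback rule — a symmetric
#' triangular whose sd is `sd_fraction` (default 0.5) times the absolute
#' point estimate — because the source trials do not report usable
#' quartiles. Quartile-based triangulars can be injected via `dists`.
#' Setting `sd_fraction = 0` collapses every distribution to a point mass
#' and the PSA reproduces the deterministic result exactly.
#'
#' With `two_level = TRUE` an optional outer/inner decomposition is run:
#' the outer loop draws parameter values, the inner loop adds sampling
#' noise around each drawn parameter (same spread), and inner results are
#' averaged per outer draw. The single-loop analysis (default) is what
#' the reported outputs reflect.
#'
#' @param scenario scenario id (e.g. `"base1"`).
#' @param params a [cea_parameters()] registry.
#' @param n_iter number of model recalculations (default 10000).
#' @param wtp willingness-to-pay threshold (EUR/QALY); default from the
#'   registry settings.
#' @param seed integer seed; fixed seeds give bit-identical results.
#' @param sd_fraction sd-to-mean fraction for the fallback triangulars;
#'   `0` for a degenerate (no-uncertainty) run.
#' @param wtp_grid thresholds for the acceptability curve (default 0 to
#'   100000 in steps of 1000).
#' @param dists optional named list overriding individual parameter
#'   distributions; names among `cost_evlt`, `cost_hls`, `util_evlt`,
#'   `util_hls`, values `"triangular"` objects.
#' @param variant EVLT variant where two laser settings are printed.
#' @param two_level run the outer/inner decomposition (off by default).
#' @param n_inner inner iterations per outer draw when `two_level = TRUE`.
#' @return object of class `"cea_psa"`: `samples` (data.frame
#'   `delta_cost`, `delta_effect`), `quadrants`, `certainty_ce`, `ceac`,
#'   plus the run metadata. Methods: `print`, `summary`, `plot`,
#'   `as.data.frame`.
#' @examples
#' ps <- psa("base1", n_iter = 500, seed = 1)
#' ps$certainty_ce
#' @export
psa <- function(scenario, params = cea_parameters(), n_iter = 10000,
                wtp = NULL, seed = NULL, sd_fraction = NULL,
                wtp_grid = seq(0, 100000, by = 1000), dists = list(),
                variant = c("evlt1", "evlt2"), two_level = FALSE,
                n_inner = 100) {
  stopifnot(inherits(params, "cea_parameters"), n_iter >= 1)
  variant <- match.arg(variant)
  oc <- scenario_outcomes(params, scenario, variant = variant)
  wtp <- wtp %||% params$settings$wtp
  sd_fraction <- sd_fraction %||% params$settings$sd_fraction
  yf <- year_fraction(oc$interval)

  means <- c(cost_evlt = oc$evlt$cost, cost_hls = oc$hls$cost,
             util_evlt = oc$evlt$utility, util_hls = oc$hls$utility)
  specs <- lapply(stats::setNames(nm = names(means)), function(p) {
    if (!is.null(dists[[p]])) {
      stopifnot(inherits(dists[[p]], "triangular"))
      dists[[p]]
    } else if (sd_fraction == 0) {
      NULL  # point mass at the mean
    } else {
      triangular_from_sd(means[[p]], sd_fraction)
    }
  })

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(as.integer(seed))
  }

  draw <- function(p, n) {
    if (is.null(specs[[p]])) rep(means[[p]], n) else rtriangular(n, specs[[p]])
  }
  if (!two_level) {
    d <- lapply(stats::setNames(nm = names(means)), draw, n = n_iter)
  } else {
    # outer: parameter uncertainty; inner: sampling noise recentred on
    # the drawn parameter, averaged per outer draw
    d <- lapply(stats::setNames(nm = names(means)), function(p) {
      outer_draws <- draw(p, n_iter)
      if (is.null(specs[[p]])) return(outer_draws)
      s <- specs[[p]]
      hw <- (s$max - s$min) / 2
      vapply(outer_draws, function(m) {
        mean(rtriangular(n_inner, triangular(m - hw, m, m + hw)))
      }, numeric(1))
    })
  }
  samples <- data.frame(
    delta_cost = d$cost_evlt - d$cost_hls,
    delta_effect = (d$util_evlt - d$util_hls) * yf)

  cv <- ceac(samples, wtp_grid)
  structure(list(
    scenario = scenario, n_iter = n_iter, seed = seed, wtp = wtp,
    sd_fraction = sd_fraction, variant = variant, two_level = two_level,
    deterministic = incremental(oc),
    samples = samples,
    quadrants = quadrant_fractions(samples, wtp),
    certainty_ce = ceac_at(samples, wtp),
    ceac = cv), class = "cea_psa")
}

#' Cost-effectiveness-plane quadrant fractions
#'
#' Partitions the sampled incremental pairs into the plane's quadrants,
#' with the north-east quadrant (EVLT costlier and more effective) split
#' at the willingness-to-pay line into acceptable (ICER at or below WTP)
#' and unacceptable parts. Boundary conventions: pairs with zero effect
#' difference and nonnegative cost difference — including the exact
#' origin — count to the north-west (comparator HL/S retained); zero
#' cost difference with nonnegative effect difference counts south-east.
#'
#' @param samples data.frame with columns `delta_cost`, `delta_effect`
#'   (or a `"cea_psa"` object).
#' @param wtp willingness-to-pay threshold (EUR/QALY).
#' @return named numeric vector of fractions `NW`, `NE_above_wtp`,
#'   `NE_below_wtp`, `SE`, `SW`, summing to 1.
#' @export
quadrant_fractions <- function(samples, wtp) {
  lab <- quadrant_labels(samples, wtp)
  n <- length(lab)
  vapply(c(NW = "NW", NE_above_wtp = "NE_above_wtp",
           NE_below_wtp = "NE_below_wtp", SE = "SE", SW = "SW"),
         function(q) sum(lab == q) / n, numeric(1))
}

# per-sample quadrant label; used for fractions and the scatter export
quadrant_labels <- function(samples, wtp) {
  if (inherits(samples, "cea_psa")) samples <- samples$samples
  dc <- samples$delta_cost; de <- samples$delta_effect
  if (length(dc) == 0L) stop("empty sample set", call. = FALSE)
  nw <- de <= 0 & dc >= 0
  se <- !nw & de >= 0 & dc <= 0
  ne <- !nw & !se & dc > 0 & de > 0
  out <- rep("SW", length(dc))
  out[nw] <- "NW"
  out[se] <- "SE"
  out[ne] <- ifelse(dc[ne] <= wtp * de[ne], "NE_below_wtp", "NE_above_wtp")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each threshold in `wtp_grid`, the probability that EVLT is the
#' optimal strategy: the fraction of iterations with positive incremental
#' net monetary benefit `wtp * delta_effect - delta_cost`. Ties (exactly
#' zero) retain the comparator, so `p_evlt + p_hls = 1` at every
#' threshold.
#'
#' @inheritParams quadrant_fractions
#' @param wtp_grid ascending vector of thresholds (EUR/QALY).
#' @return data.frame with columns `wtp`, `p_evlt`, `p_hls`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 100000, by = 1000)) {
  if (inherits(samples, "cea_psa")) samples <- samples$samples
  if (nrow(samples) == 0L) stop("empty sample set", call. = FALSE)
  p <- vapply(wtp_grid, function(w) ceac_at(samples, w), numeric(1))
  data.frame(wtp = wtp_grid, p_evlt = p, p_hls = 1 - p)
}

ceac_at <- function(samples, wtp) {
  mean(wtp * samples$delta_effect - samples$delta_cost > 0)
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("<cea_psa> scenario %s: %d iterations%s, WTP %s EUR/QALY\n",
              x$scenario, x$n_iter,
              if (!is.null(x$seed)) sprintf(" (seed %d)", x$seed) else "",
              format(x$wtp, big.mark = ",")))
  q <- x$quadrants
  cat(sprintf("  HL/S dominates (NW)          : %5.1f %%\n", 100 * q[["NW"]]))
  cat(sprintf("  EVLT costlier, ICER > WTP    : %5.1f %%\n",
              100 * q[["NE_above_wtp"]]))
  cat(sprintf("  EVLT costlier, ICER <= WTP   : %5.1f %%\n",
              100 * q[["NE_below_wtp"]]))
  cat(sprintf("  EVLT dominates (SE)          : %5.1f %%\n", 100 * q[["SE"]]))
  cat(sprintf("  both lower (SW)              : %5.1f %%\n", 100 * q[["SW"]]))
  cat(sprintf("  P(EVLT cost-effective at WTP): %5.2f %%\n",
              100 * x$certainty_ce))
  invisible(x)
}

#' @export
as.data.frame.cea_psa <- function(x, ...) x$samples

#' @export
summary.cea_psa <- function(object, ...) {
  s <- object$samples
  list(scenario = object$scenario, n_iter = object$n_iter,
       mean_delta_cost = mean(s$delta_cost),
       mean_delta_effect = mean(s$delta_effect),
       quadrants = object$quadrants,
       certainty_ce = object$certainty_ce)
}

#' @export
plot.cea_psa <- function(x, which = c("plane", "ceac"), ...) {
  which <- match.arg(which)
  if (which == "plane") {
    graphics::plot(x$samples$delta_effect, x$samples$delta_cost,
                   pch = ".", col = grDevices::adjustcolor("steelblue", 0.4),
                   xlab = "incremental effect (QALY, EVLT - HL/S)",
                   ylab = "incremental cost (EUR)",
                   main = sprintf("PSA scatter: %s", x$scenario), ...)
    graphics::abline(h = 0, v = 0, col = "grey60")
    graphics::abline(a = 0, b = x$wtp, lty = 2, col = "grey30")
  } else {
    graphics::plot(x$ceac$wtp, x$ceac$p_evlt, type = "l", ylim = c(0, 1),
                   xlab = "willingness to pay (EUR/QALY)",
                   ylab = "P(strategy optimal)",
                   main = sprintf("Acceptability curve: %s", x$scenario), ...)
    graphics::lines(x$ceac$wtp, x$ceac$p_hls, lty = 2)
    graphics::abline(v = x$wtp, col = "grey60", lty = 3)
    graphics::legend("right", legend = c("EVLT", "HL/S"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}
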