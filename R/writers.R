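#' Export analysis results
#'
#' `write_cea()` writes the per-scenario result table as CSV and a JSON
#' summary (dominance membership and counts, WTP). `write_psa()` writes
#' the sampled incremental pairs with their quadrant labels
#' (`<prefix>_scatter.csv`), the acceptability curve
#' (`<prefix>_ceac.csv`) and a JSON summary of the quadrant fractions
#' and certainty.
#'
#' @param x a `"cea"` or `"cea_psa"` object.
#' @param prefix output path prefix (directories must exist).
#' @return invisibly, the vector of files written.
#' @export
write_cea <- function(x, prefix) {
  stopifnot(inherits(x, "cea"))
  files <- c(paste0(prefix, "_results.csv"),
             paste0(prefix, "_summary.json"))
  utils::write.csv(x$results, files[1], row.names = FALSE)
  rep <- dominance_report(x)
  jsonlite::write_json(
    list(wtp = x$wtp,
         counts = lapply(rep, length),
         membership = rep),
    files[2], auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

#' @rdname write_cea
#' @export
write_psa <- function(x, prefix) {
  stopifnot(inherits(x, "cea_psa"))
  files <- c(paste0(prefix, "_scatter.csv"),
             paste0(prefix, "_ceac.csv"),
             paste0(prefix, "_psa.json"))
  scatter <- cbind(iter = seq_len(nrow(x$samples)), x$samples,
                   quadrant = quadrant_labels(x$samples, x$wtp))
  utils::write.csv(scatter, files[1], row.names = FALSE)
  utils::write.csv(x$ceac, files[2], row.names = FALSE)
  jsonlite::write_json(
    list(scenario = x$scenario, n_iter = x$n_iter, seed = x$seed,
         wtp = x$wtp, quadrant_fractions = as.list(x$quadrants),
         certainty_ce = x$certainty_ce),
    files[3], auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}
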