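# Shared registry load. The shipped registry intentionally warns about
# the two published total-cost rows that do not reconstruct exactly from
# direct + TRW x rate; tests that are not about that warning load quietly.
load_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- suppressWarnings(cea_parameters())
    cache
  }
})

# Minimal all-zero-slope coefficient set for mapping tests
constant_coeffs <- function(intercept = 0.9) {
  list(intercept = intercept,
       slopes = stats::setNames(as.list(numeric(8)),
                                c("PF", "RP", "BP", "GH",
                                  "VT", "SF", "RE", "MH")),
       label = "constant")
}
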