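Package: veincea
Title: Cost-Utility Analysis of Endovenous Laser Ablation Versus Surgery
    for Varicose Veins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic cost-utility evaluation of endovenous laser
    ablation (EVLT) against high ligation and stripping (HL/S) for
    uncomplicated primary varicose veins. Implements utility derivation
    from trial quality-of-life summaries (SF-36 to HUI2 mapping, visual
    analogue scale to standard gamble power transformation, VAS-based
    utility decrements), interval-weighted QALY conversion, a cost model
    with productivity loss from time to return to work, incremental
    cost-effectiveness and dominance classification over a registry of
    named scenarios, and probabilistic sensitivity analysis with
    triangular parameter distributions, cost-effectiveness plane quadrant
    accounting and acceptability curves. A synthetic patient-level trial
    generator supports end-to-end testing without access to the source
    trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
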