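---
title: "Model and methods: EVLT versus surgery cost-utility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: EVLT versus surgery cost-utility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veincea)
```

## The decision problem

Two strategies for uncomplicated primary varicose veins with
saphenofemoral reflux: endovenous laser ablation (EVLT) and conventional
high ligation and stripping (HL/S). Neither affects survival over the
short horizon considered (up to six months), so the comparison is driven
entirely by costs and health-related quality of life. Costs and effects
are not discounted at this horizon, and complication disutilities are
assumed equivalent between arms and excluded — both standard positions
for short-horizon models of this procedure pair.

The model is a straight two-strategy cost-utility comparison, evaluated
over a registry of 25 scenarios (3 base cases and 22 alternatives) that
cross different utility sources, follow-up intervals and costing bases.

## Costs

Each strategy's expected cost is either its direct procedure cost or a
total cost adding productivity loss:

$$C = C_\text{direct} + \text{TRW} \times r$$

with TRW the time to return to work in days and $r$ the daily
productivity rate. The registry's published total-cost rows that state
an integer TRW reconstruct exactly, to the cent, with $r = 285$ €/day,
so that value ships as the default (`settings.daily_productivity_rate`,
overridable). Two rows (the 7.0/7.6-day totals) imply TRW values of
7.04 and 7.58 days instead; the loader warns about them and retains the
printed totals as authoritative.

## Utilities and QALYs

Three derivation pathways, all exposed as small pure functions:

* **SF-36 → HUI2** (`hui2_from_sf36()`): a linear map
  $u = \beta_0 + \sum_d \beta_d x_d$ over the eight SF-36 domain scores
  (each 0–100). The published regression coefficients for this map are
  not redistributable here, so the operator takes injected coefficients
  and the parameter file ships a clearly labelled illustrative-synthetic
  set used only by the simulated-trial pipeline; the registry's HUI2
  scores for the real scenarios are stored inputs, not recomputed.
  Outputs are deliberately not clamped: several registry scores exceed
  1, and they are carried as printed.
* **VAS → SG** (`sg_from_vas()`): rescale a 0–100 VAS rating to
  $v \in [0,1]$ and apply the power curve $u = 1-(1-v)^{b}$. The
  exponent defaults to the conventional population-level estimate
  $b = 2.27$ (`settings.torrance_exponent`); $b = 1$ recovers the raw
  rescaled VAS.
* **VAS pain decrement** (`kovacs_disutility()`): a linear
  $-0.035$ utility per mm of VAS pain
  (`settings.kovacs_slope`), giving nonpositive decrements.

A utility observed at follow-up interval $t$ contributes
$\text{QALY} = u \cdot f(t)$ with year fractions $f$: days/364 (a
52-week year of 7-day weeks), weeks/52, months/12. These conventions are
the ones the registry's printed QALY column implies exactly (e.g.
$-0.28 \times 7/364 = -0.0053846$; $1.44 \times 3/12 = 0.36$). Day-28
rows are weighted as one month (1/12 year): the printed
$-0.039 \rightarrow -0.00325$ conversion and the per-arm
cost-effectiveness ratios of those scenarios
($924.67 / (-0.087/12) = -127{,}541$) reproduce only under the monthly
convention, so the package adopts it for those rows.

### Printed-QALY validation

`validate_qalys()` recomputes all 22 printed QALY cells.
Seventeen reproduce within $2\times10^{-4}$. Five do not and are frozen
in `qaly_discrepancies()`:

```{r}
qaly_discrepancies()
```

Scenario QALYs are therefore always recomputed from utility ×
year-fraction rather than read from the printed column — necessary for
the six-month alternative scenarios whose printed cells are both rounded
to 0.735 although the arms differ (1.467 vs 1.473), which would
otherwise erase a real dominance distinction.

## Incremental analysis and dominance

Deltas are EVLT − HL/S throughout. The classifier uses **weak
dominance**: a strategy is dominated when the rival is no worse on both
cost and effect and strictly better on at least one. The weak form is
load-bearing — several scenarios have exactly equal QALYs and differ
only in cost. Equal cost *and* effect is a trade-off. The ICER
$\Delta C/\Delta E$ is reported only for trade-offs; dominated and
zero-effect comparisons return `NA` with a typed reason. For the two
scenarios where both arms have negative QALYs, the plain ratio of deltas
is reported, as in the source analysis.

Where the registry prints two laser settings (12 W pulsed "EVLT1" and
14 W continuous "EVLT2"), classification uses EVLT1; EVLT2 outcomes are
computed and reported alongside.

The per-arm incremental report (`icer_table()`) consumes the registry's
`icer_table` block, which stores the published per-arm expected costs
and effects verbatim. Several of those differ from what the cost and
utility rows reconstruct (the provenance is not documented in the
source); the printed values are treated as authoritative inputs, and the
eight published ICERs then reproduce within 0.1%.

## Probabilistic sensitivity analysis

Each of 10,000 iterations redraws four parameters — both strategies'
cost and utility — independently from triangular distributions,
recomputes QALYs and deltas, and the cloud is summarized three ways:

* **Quadrant fractions** of the cost-effectiveness plane, with the NE
  quadrant (EVLT costlier and more effective) split at the
  willingness-to-pay line. Boundary conventions: $\Delta E = 0$ with
  $\Delta C \ge 0$ — including the exact origin — counts NW (the
  comparator HL/S is retained); $\Delta C = 0$ with $\Delta E \ge 0$
  counts SE.
* **Certainty**: the fraction of iterations with positive incremental
  net monetary benefit $\lambda \Delta E - \Delta C$ at the configured
  threshold. This equals the acceptability curve at that threshold by
  construction (identical indicator); ties of exactly zero retain HL/S.
* **CEAC** over a grid of thresholds (default €0–100,000 in €1,000
  steps), with $P_\text{EVLT} + P_\text{HLS} = 1$ everywhere.

Distribution construction follows two rules: from quartiles, the span is
the mean ± twice the mean-to-quartile distance (mode at the mean); from
a bare point estimate, a symmetric triangular with
$\mathrm{sd} = 0.5 \times |\text{mean}|$, i.e. half-width
$\mathrm{sd}\sqrt{6}$ since a symmetric triangular of width $w$ has
variance $w^2/24$. The source trials report no usable quartiles, so the
sd fallback is the default for every parameter (`settings.sd_fraction`);
quartile-based or explicit triangulars can be injected per parameter.
Utilities are not clamped at 1 (the registry's scores exceed 1) and
sampled costs may in principle go negative under the wide fallback —
both faithful consequences of the stated rules rather than artifacts to
correct. Setting `sd_fraction = 0` collapses every distribution to a
point mass, and the PSA reproduces the deterministic deltas exactly —
used as an invariant across all 25 scenarios.

Because the fallback spreads are assumptions, the published certainty
percentages (12.49% base case 1, 0.46% base case 2, 98.8% alternative
11) are not point-reproducible; what is reproducible is direction, and
the suite checks it: across ten seeds at 10,000 iterations, base case 2
stays below 50% certainty and alternative 11 above. The "two-dimensional
Monte Carlo" label is implemented as the single parameter-uncertainty
loop the reported outputs reflect; an optional outer/inner
decomposition (parameter draws outside, sampling noise of the same
spread recentred on each draw inside, averaged per outer draw) is
available behind `two_level = TRUE` but off by default.

Sampling uses the closed-form inverse CDF of the triangular; moments are
tested against the closed forms $(a+m+b)/3$ and
$(a^2+m^2+b^2-am-ab-mb)/18$ at $n = 10^5$ within three standard errors.
Fixed seeds give bit-identical results; the RNG state is restored on
exit so a seeded call does not perturb the caller's stream.

## Synthetic trial generator

`generate_cohort()` emulates the patient-level randomized-trial records
the published summaries collapse: per arm, TRW from a truncated normal
at the stated mean/sd/range (rejection sampling), VAS and the eight
SF-36 domains from truncated normals on [0, 100], a constant per-arm
direct cost, and the derived total cost. Two packaged designs mirror
the source TRW summaries (7.0 ± 6.0 days range 1–31 vs 7.6 ± 4.9 range
1–28; and 7.0 vs 12.4 days). VAS means default to 8 mm — the value whose
decrement matches the registry's −0.28 — with sd 5 mm, and SF-36 domain
means/sds are set to a plausible post-operative profile (e.g. PF 75 ±
20); the sources print no patient-level moments for these, so they are
package choices, fixed once.

Limitations to read passing tests correctly: domains are drawn
independently (real SF-36 domains correlate strongly); costs are
constant within arm (real resource use varies); there is no dropout or
longitudinal structure. The generator therefore validates the
*pipeline* — that summaries of patient-level data flow correctly through
mapping, costing and PSA — not distributional realism. Truncation
shifts means upward (a normal(7, 6) truncated at 1 day has mean ≈ 9.0),
so recovery tests compare against closed-form truncated-normal
expectations, not the nominal design means. The parameter-recovery
check runs at $n = 10^4$ per arm and recovers design-implied expected
cost and QALY within 1%.

## Numerical and design choices

* Currency in euros at cent precision; no discounting.
* Problem sizes in the test suite: PSA invariants at 10,000 iterations,
  sampler moments at $10^5$ draws, synthetic recovery at $10^4$ patients
  per arm — the full suite runs in a few seconds.
* The parameter file is YAML, mapping the published tables row for row;
  `registry_tables()` exports the parsed registry as CSV for audit, and
  loading is all-or-nothing (an invalid document yields no partial
  registry).
* Scenario `alt20` runs and is reported but is excluded from the
  published 8/5/8 membership comparison, which does not list it; by the
  classifier it is a trade-off (direct costs, EVLT1 quality of life
  better).
* Ties in NMB resolve to HL/S (comparator retained), making the
  acceptability curve's two probabilities complementary by construction.
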