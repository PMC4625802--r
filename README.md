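# veincea

Cost-utility analysis of endovenous laser ablation (EVLT) versus high
ligation and stripping (HL/S) for uncomplicated primary varicose veins.

Varicose-vein treatment is a high-volume procedure, and the minimally
invasive laser alternative carries extra equipment cost against a
possibly faster recovery. `veincea` implements a decision-analytic
comparison of the two strategies for health economists and methods
students: it encodes the published trial-level cost and quality-of-life
summaries as a validated parameter registry, derives utilities along
three pathways, and evaluates 25 named scenarios deterministically and
probabilistically.

## The model

For each strategy *s* and scenario, an expected cost *C_s* (direct
procedure cost, optionally plus productivity loss `TRW × r` where TRW is
the time to return to work in days and *r* = €285/day) and an expected
effect *E_s* in QALYs, computed as a utility score weighted by the
follow-up interval's year fraction (days/364, weeks/52, months/12).
Utilities come from:

* SF-36 profiles mapped to Health Utilities Index Mark II (HUI2) scores
  through an injected linear regression (`hui2_from_sf36()`),
* visual analogue scale ratings transformed to standard-gamble utilities
  by the power curve `u = 1 − (1 − v)^2.27` (`sg_from_vas()`), or
* VAS pain decrements at −0.035 utility per mm (`kovacs_disutility()`).

The incremental comparison uses ΔC = C_EVLT − C_HLS and
ΔE = E_EVLT − E_HLS, the ICER ΔC/ΔE where neither strategy weakly
dominates, net monetary benefit `NMB = λE − C` at a willingness-to-pay
threshold λ (default €50,000/QALY), and weak dominance (no worse on both
axes, strictly better on one). The probabilistic analysis redraws every
cost and utility from triangular distributions — built from quartiles by
the doubling rule, or symmetric with sd = 0.5 × mean when only a point
estimate exists — over 10,000 model recalculations, and summarizes the
(ΔC, ΔE) cloud as cost-effectiveness-plane quadrant fractions and an
acceptability curve.

## Worked example

```r
library(veincea)
params <- cea_parameters()     # packaged registry (warns about two
                               # published totals that don't reconstruct)
fit <- cea(params)
summary(fit)
#> Dominance over 25 scenario(s):
#>   EVLT dominated by HL/S : 11 (base1, base2, base3, alt4, alt5, alt6, alt16, alt17, alt18, alt22, alt24)
#>   HL/S dominated by EVLT : 5 (alt9, alt13, alt15, alt19, alt21)
#>   no clear dominance     : 9 (alt7, alt8, alt10, alt11, alt12, alt14, alt20, alt23, alt25)
```

All three base cases are weakly dominated: EVLT costs €466.66 more in
direct costs and yields the same or fewer QALYs at every follow-up. Of
the 21 alternative scenarios the published dominance tables enumerate
(everything except `alt20`), 8 are EVLT-dominated, 5 HL/S-dominated and
8 trade-offs — the extra entries above are the three base cases and
`alt20`. For a trade-off scenario the ICER report gives the per-arm
and incremental view:

```r
icer_table(params, "alt14")
#>      id strategy    cost effect ce_ratio delta_cost delta_effect     icer
#> 1 alt14      HLS 3028.17  0.355 8530.056         NA           NA       NA
#> 2 alt14     EVLT 3332.13  0.380 8768.763     303.96        0.025 12158.40
```

i.e. EVLT buys 0.025 extra QALYs for €303.96, about €12,158 per QALY —
well under the €50,000 threshold. The probabilistic analysis quantifies
how certain that conclusion is:

```r
ps <- psa("base1", params, n_iter = 10000, seed = 1)
ps
#> <cea_psa> scenario base1: 10000 iterations (seed 1), WTP 50,000 EUR/QALY
#>   HL/S dominates (NW)          :  37.1 %
#>   EVLT costlier, ICER > WTP    :   5.6 %
#>   EVLT costlier, ICER <= WTP   :  27.8 %
#>   EVLT dominates (SE)          :  13.7 %
#>   both lower (SW)              :  15.8 %
#>   P(EVLT cost-effective at WTP): 42.74 %
plot(ps, "ceac")
```

Quadrant fractions are fractions of iterations in each region of the
cost-effectiveness plane (NW: HL/S less costly and more effective); the
final line is the acceptability-curve value at the threshold. With the
default sd = 0.5 × mean spreads the cloud is wide; tighter,
quartile-based triangulars can be injected per parameter via `dists`.

Synthetic patient-level trials (arm assignment, SF-36 domains, VAS, TRW,
costs) for end-to-end pipeline testing:

```r
cohort <- generate_cohort(design_rasmussen(500), seed = 1)
summarize_cohort(cohort)
```

A command-line wrapper lives at `inst/cli/veincea`
(`run`, `report`, `simulate-trial` subcommands).

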