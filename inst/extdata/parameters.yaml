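# Default model parameters for the EVLT vs HL/S cost-utility analysis.
# Utilities and costs are the published summary inputs of the source
# randomized trials; the icer_table block carries the per-arm expected
# costs/effects printed alongside the trade-off scenarios, which take
# precedence over reconstruction where the two disagree.
meta:
  label: "EVLT vs HL/S varicose-vein cost-utility model"
  currency: EUR
settings:
  daily_productivity_rate: 285.00   # EUR per sick-leave day, reconstructed
  wtp: 50000                        # EUR per QALY decision threshold
  torrance_exponent: 2.27           # VAS -> SG power transform
  kovacs_slope: 0.035               # utility decrement per mm VAS
  sd_fraction: 0.5                  # PSA fallback: sd = 0.5 * mean

utilities:
  rasmussen_1mo:
    kind: hui2
    interval: {value: 1, unit: months}
    source: "Rasmussen trial, SF-36 derived HUI2"
    evlt: 1.360
    hls: 1.430
    printed_qaly: {evlt: 0.1133, hls: 0.1192}
  rasmussen_3mo:
    kind: hui2
    interval: {value: 3, unit: months}
    source: "Rasmussen trial, SF-36 derived HUI2"
    evlt: 1.440
    hls: 1.470
    printed_qaly: {evlt: 0.3600, hls: 0.3675}
  rasmussen_6mo:
    kind: hui2
    interval: {value: 6, unit: months}
    source: "Rasmussen trial, SF-36 derived HUI2"
    evlt: 1.470
    hls: 1.470
    printed_qaly: {evlt: 0.735, hls: 0.735}
  mekako_6wk:
    kind: hui2
    interval: {value: 6, unit: weeks}
    source: "Mekako trial, SF-36 derived HUI2"
    evlt: 1.480
    hls: 1.390
    printed_qaly: {evlt: 0.1709, hls: 0.1605}
  mekako_12wk:
    kind: hui2
    interval: {value: 12, unit: weeks}
    source: "Mekako trial, SF-36 derived HUI2"
    evlt: 1.520
    hls: 1.420
    printed_qaly: {evlt: 0.3510, hls: 0.3279}
  rasmussen_6mo_alt:
    kind: hui2
    interval: {value: 6, unit: months}
    source: "Rasmussen trial, SF-36 derived HUI2 (alternative estimates)"
    evlt: 1.467
    hls: 1.473
    printed_qaly: {evlt: 0.735, hls: 0.735}
  darwood_day7:
    kind: vas_disutility
    interval: {value: 7, unit: days}
    source: "Darwood trial, VAS pain decrement, day 7"
    evlt: -0.28        # EVLT1, 12 W pulsed
    evlt2: -0.175      # EVLT2, 14 W continuous
    hls: -0.28
    printed_qaly: {evlt: -0.0053846, evlt2: -0.0033654, hls: -0.0053846}
  darwood_day1_7:
    kind: vas_disutility
    interval: {value: 7, unit: days}
    source: "Darwood trial, VAS pain decrement, mean of days 1-7"
    evlt: -0.385
    evlt2: -0.630
    hls: -0.49
    printed_qaly: {evlt: -0.0074038, evlt2: -0.0121154, hls: -0.0094231}
  kalteis_day7:
    kind: vas_disutility
    interval: {value: 7, unit: days}
    source: "Kalteis trial, VAS pain decrement, day 7"
    evlt: -0.606
    hls: -0.602
    printed_qaly: {evlt: -0.0126923, hls: -0.0115769}
  kalteis_day28:
    kind: vas_disutility
    # Day 28 is weighted as one month (1/12 year): the printed QALYs
    # (-0.039 -> -0.00325) and per-arm cost-effectiveness ratios only
    # reproduce under the monthly convention.
    interval: {value: 1, unit: months}
    source: "Kalteis trial, VAS pain decrement, day 28"
    evlt: -0.039
    hls: -0.087
    printed_qaly: {evlt: -0.00325, hls: -0.00715}

costs:
  rasmussen_direct:
    basis: direct
    source: "Rasmussen trial, procedure costs"
    evlt: {direct_cost: 1390.66}
    hls: {direct_cost: 924.00}
  rasmussen_total:
    basis: total
    source: "Rasmussen trial, totals incl. productivity loss"
    evlt: {direct_cost: 1390.66, trw_days: 7.0, total_cost: 3396.40}
    hls: {direct_cost: 924.00, trw_days: 7.6, total_cost: 3084.50}
  reactive_total:
    basis: total
    source: "REACTIVE trial, totals incl. productivity loss"
    evlt: {direct_cost: 1390.66, trw_days: 7.0, total_cost: 3396.40}
    hls: {direct_cost: 924.00, trw_days: 12.4, total_cost: 4458.00}
  darwood_total:
    basis: total
    source: "Darwood TRW on Rasmussen direct costs"
    evlt: {direct_cost: 1390.66, trw_days: 4, total_cost: 2530.66}
    hls: {direct_cost: 924.00, trw_days: 17, total_cost: 5769.00}
  kalteis_total:
    basis: total
    source: "Kalteis TRW on Rasmussen direct costs"
    evlt: {direct_cost: 1390.66, trw_days: 20, total_cost: 7090.66}
    hls: {direct_cost: 924.00, trw_days: 14, total_cost: 4914.00}

# Scenario ids -> (utility row, cost row). base1-base3 are the base cases;
# alt4-alt25 the alternative analyses.
scenarios:
  base1: {utility: rasmussen_1mo, cost: rasmussen_direct}
  base2: {utility: rasmussen_3mo, cost: rasmussen_direct}
  base3: {utility: rasmussen_6mo, cost: rasmussen_direct}
  alt4:  {utility: rasmussen_1mo, cost: rasmussen_total}
  alt5:  {utility: rasmussen_3mo, cost: rasmussen_total}
  alt6:  {utility: rasmussen_6mo, cost: rasmussen_total}
  alt7:  {utility: rasmussen_1mo, cost: reactive_total}
  alt8:  {utility: rasmussen_3mo, cost: reactive_total}
  alt9:  {utility: rasmussen_6mo, cost: reactive_total}
  alt10: {utility: mekako_6wk,  cost: rasmussen_direct}
  alt11: {utility: mekako_12wk, cost: rasmussen_direct}
  alt12: {utility: mekako_6wk,  cost: rasmussen_total}
  alt13: {utility: mekako_6wk,  cost: reactive_total}
  alt14: {utility: mekako_12wk, cost: rasmussen_total}
  alt15: {utility: mekako_12wk, cost: reactive_total}
  alt16: {utility: rasmussen_6mo_alt, cost: rasmussen_direct}
  alt17: {utility: rasmussen_6mo_alt, cost: rasmussen_total}
  alt18: {utility: darwood_day7,   cost: rasmussen_direct}
  alt19: {utility: darwood_day7,   cost: darwood_total}
  alt20: {utility: darwood_day1_7, cost: rasmussen_direct}
  alt21: {utility: darwood_day1_7, cost: darwood_total}
  alt22: {utility: kalteis_day7,   cost: rasmussen_direct}
  alt23: {utility: kalteis_day28,  cost: rasmussen_direct}
  alt24: {utility: kalteis_day7,   cost: kalteis_total}
  alt25: {utility: kalteis_day28,  cost: kalteis_total}

# Published per-arm expected costs and effects for the trade-off scenarios
# (incremental cost-effectiveness report). These printed values are
# authoritative inputs; several differ from what the cost/utility rows
# above reconstruct (provenance of the differences is not documented in
# the source).
icer_table:
  alt7:
    hls:  {cost: 5756.33, effect: 0.1192}
    evlt: {cost: 2676.89, effect: 0.1133}
  alt8:
    hls:  {cost: 5756.33, effect: 0.3675}
    evlt: {cost: 2676.89, effect: 0.3600}
  alt10:
    hls:  {cost: 924.67,  effect: 0.1605}
    evlt: {cost: 1363.55, effect: 0.1709}
  alt11:
    hls:  {cost: 924.67,  effect: 0.3279}
    evlt: {cost: 1363.55, effect: 0.3510}
  alt12:
    hls:  {cost: 3028.17, effect: 0.1605}
    evlt: {cost: 3332.13, effect: 0.1709}
  alt14:
    hls:  {cost: 3028.17, effect: 0.355}
    evlt: {cost: 3332.13, effect: 0.380}
  alt23:
    hls:  {cost: 924.67,  effect: -0.00725}
    evlt: {cost: 1363.55, effect: -0.00325}
  alt25:
    hls:  {cost: 4971.33, effect: -0.00725}
    evlt: {cost: 7030.22, effect: -0.00325}

# SF-36 -> HUI2 linear mapping coefficient sets. The published mapping
# coefficients are not distributed with this package; the default set is
# an illustrative synthetic stand-in used by the simulated-trial pipeline.
sf36_hui2_coefficients:
  illustrative-synthetic:
    label: "illustrative-synthetic (not the published mapping)"
    intercept: 0.40
    slopes: {PF: 0.0040, RP: 0.0008, BP: 0.0012, GH: 0.0016,
             VT: 0.0008, SF: 0.0010, RE: 0.0008, MH: 0.0020}
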