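---
title: "Model structure, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vilocea)
```

This vignette documents the model the package implements, the conventions
behind every tunable number, and the choices made where the design was
genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The decision problem

Critically ill COVID-19 patients on invasive mechanical ventilation who
receive immunomodulators (tocilizumab or baricitinib) have high short-term
mortality. The model compares two strategies that differ only in the
addition of vilobelimab, an anti-C5a antibody given in up to six infusions
during hospitalization: 60-day survival 0.82 with vilobelimab versus 0.51
with standard of care alone, drug cost $6,350 per administration (mean 4.8
administrations), and slightly less renal replacement therapy (9.6% over
6.8 days vs 15.7% over 9.4 days at $2,000/day). Both arms share the ICU
hospitalization cost of $100,461 and the cost of the immunomodulators
themselves is deliberately excluded: it is identical in both arms and
cancels from every incremental quantity.

## Acute phase

The acute phase is a decision tree spanning `acute_phase_cycles` monthly
cycles (default 2, covering the 60-day survival endpoint). Conventions:

* **Costing.** The full ICU cost is charged to every patient, survivor or
  decedent, in both arms; this is the reading under which the per-arm cost
  totals reconcile arithmetically with the unit costs above. RRT affects
  cost only; no utility consequence is attached to it.
* **Drug administrations.** The mean number of administrations (4.8) is
  exposed in the configuration. It is the value at which the drug cost
  component equals 4.8 × $6,350 = $30,480 per treated patient; the maximal
  authorized schedule is 6.
* **Utility in hospital.** Age-band utility minus the
  mechanical-ventilation disutility of 0.56, floored at zero (0.84 − 0.56 =
  0.28 at entry age 58.6). The disutility is read as a *decrement* because
  that is what a disutility is; reading 0.56 as the absolute in-hospital
  utility would instead require it to exceed some age-band utilities after
  age 80.
* **Death timing.** Deaths are assumed uniform over the acute phase, so
  decedents accrue half of its life years and QALYs — the usual
  within-trial convention. The acute contribution is small (~0.15 LY,
  ~0.04 QALY per patient) relative to the lifetime totals.

## Post-discharge Markov cohort

Survivors enter a two-state alive/dead cohort at age `start_age +
acute_phase_cycles/12`.

* **Cycle length and mortality.** Monthly cycles; the annual life-table
  probability `q` at the cohort's current integer age (floor of the exact
  age) converts to monthly via the constant-hazard-within-year formula
  `1 − (1 − q)^{1/12}`, so twelve monthly applications reproduce `q`
  exactly. The naive `q/12` alternative would not.
* **Half-cycle correction.** Life-year increments average adjacent-cycle
  state membership (trapezoid on the trace): `(a_t + a_{t+1})/2 · 1/12`.
  For a constant monthly hazard `p` this gives the closed form
  `(1/p − 1/2)/12`, which the test suite checks to `1e-9` relative error.
* **Utilities.** Age bands (closed-open intervals): 0.870 below age 50,
  0.840 for 50–59, 0.820 for 60–69, 0.790 for 70–79, 0.740 at 80 and
  above. The published utility source starts its bands at age 40 and tops
  out at "over 80"; extending the nearest band downward (needed for
  sensitivity analyses at entry age 22) and treating 80+ as one band are
  the package's own extensions. Post-discharge disutilities of 0.130,
  0.067, 0.062 and 0.026 apply in years 1–4 after discharge (year *k* on
  `[k−1, k)`), then expire. Utilities are floored at zero.
* **Discounting.** Costs all fall in the acute phase; outcomes are
  discounted at `annual_discount_rate`, default **3%/year** — the
  long-standing US panel convention — applied per monthly cycle as
  `(1+r)^{−t/12}` with `t` counted from model entry. Life years are
  reported undiscounted, QALYs and evLYs discounted: that is the only
  combination under which the reported per-arm life-year and QALY totals
  can coexist at plausible utilities.
* **Horizon.** Lifetime, operationalized as age 100 (the bundled table's
  terminal age); the trace also stops once the surviving fraction falls
  below `1e-12`, which matters only for the synthetic long-horizon tables
  used in testing.

## Equal-value life years

The evLY metric values survival gains at a fixed reference utility so that
a lower quality of life does not discount added survival:
`evLY = u_ref × (discounted LY)`, with `u_ref = 0.851` by default
(configurable). A common alternative defines evLYG only incrementally —
gained life years valued at `u_ref` — but on the incremental scale the two
definitions coincide (`ΔevLY = u_ref × ΔLY_disc`), so the package reports
per-arm evLY and their difference from the single implementation.

## The bundled life table

No official life table ships with the package (none is redistributed);
instead `inst/extdata/lifetable_us_synthetic.tsv` is generated by
`data-raw/lifetable.R` from the package's own Gompertz–Makeham generator:
hazard `h(x) = 5·10⁻⁴ + a·e^{0.09x}`, slope typical of adult US mortality,
with `a = 4.5488·10⁻⁵` calibrated so that the base-case cohort discharged
at age 58.77 has a remaining undiscounted life expectancy of 22.19 years
under the package's own engine — consistent with 2020–2021-era US period
mortality at that age. The table is US-*like*: it has no infant-mortality
hump and no accident bump in the 20s, which is immaterial here because the
youngest age the model ever consults is the sensitivity-analysis entry age
of 22. Users with an official table supply it as a two-column `age`/`q`
text file.

## Uncertainty analysis

* **Ranges to distributions.** The parameter table publishes point
  estimates with low–high ranges; these are read as 95% intervals, `sd =
  (high − low)/3.92`. Whether the original ranges were 95% CIs or min/max
  is not stated; the 95% reading is standard PSA practice when only
  intervals are printed. Utility parameters publish SDs directly and those
  are used verbatim.
* **Families.** Beta for probabilities and utilities, gamma for durations
  (method of moments in both cases; fitted moments are reproduced exactly
  and checked by simulation), normal for age truncated to the observed
  range [22, 79] by resampling. Ages outside the trial range are
  unsupported, and truncation-by-resampling neither clumps mass at the
  bounds nor biases the interior shape. Note the truncation shifts the
  distribution's mean (to ≈56.5 from the base 58.6); convergence
  diagnostics therefore compare draw means to the *fitted distribution's*
  analytic mean.
* **Fixed costs.** The three unit costs carry no distribution in the
  source table ("NA"); they are held fixed in the PSA and varied only in
  the one-way analysis. The ICU cost, being common to both arms, cannot
  move the ICER at all — its tornado span is zero by construction.
* **The inverted RRT range.** The published RRT duration for the
  intervention arm is 6.8 days with range "7.8 to 8.8" — the base lies
  outside its own range, a presumed typographical error. The bundled
  configuration substitutes the symmetric 5.8–7.8 range;
  `load_parameters(..., on_inverted_range = "keep")` loads the values as
  printed for anyone wanting them.
* **One-way DSA.** Each ranged parameter is set to its low and high bound
  with everything else at base; results sort by ICER span, ties broken by
  parameter path. In each PSA draw the sampled age shifts model entry for
  both arms jointly, while clinical parameters are sampled per arm
  independently; draws where reference survival exceeds intervention
  survival are retained — the model is coherent either way and rejecting
  them would bias the estimate.
* **Reproducibility.** One seeded generator; parameters are sampled in the
  order they appear in the configuration, one block per parameter, so a
  given `(seed, n)` is bit-reproducible.
* **CEAC.** Fraction of draws with strictly positive net monetary benefit
  on a WTP grid ($0–150,000 in $1,000 steps by default); ties count as not
  accepted.

## Numerical choices and degenerate inputs

* ICERs are computed on unrounded totals; rounding happens only in printed
  summaries. Dominance ("dominant"/"dominated") replaces the ICER when the
  signs make a ratio meaningless, and `|ΔQALY| < 1e-12` yields an
  undefined-ICER flag rather than a huge ratio.
* Age-band boundaries resolve to the older band (closed-open intervals);
  the life-table lookup age is the floor of the exact age.
* Validation collects *all* failures before reporting, rejects unknown
  configuration keys by name, and the life-table reader reports malformed
  lines by line number.

## Problem sizes in the test suite

The suite runs the full lifetime model (≈495 monthly cycles) throughout,
a 10,000-draw PSA in the end-to-end tests (matching the analysis's own
`n_psa_draws`), 10⁶-variate simulations for the distribution-fit checks,
and 100 randomized parameter fixtures for the validation sweep. These
sizes keep the whole suite under a minute on one core while leaving
Monte-Carlo error far below the tolerances tested.

## Known limitations

* The synthetic life table reproduces the *level* of adult US mortality at
  the calibration age but not an official table's exact age profile;
  absolute QALY/LY totals shift by a few percent across plausible table
  vintages, while cost results are unaffected.
* With a lifetime horizon and 3%/year discounting, lowering the entry age
  to 22 compounds the survival gain over many decades, so the entry-age
  tornado bar is wide — comparable to the intervention-survival bar. Other
  implementations of this comparison report a narrower age span than this
  model produces; their handling of the age scenario is not documented,
  and no US-like life table brings this model's age span below the
  survival span under a lifetime horizon.
* No post-discharge healthcare costs, no excess post-COVID mortality
  (long-term life expectancy is assumed unaffected by the ICU stay), no
  correlation structure in the PSA, and exactly two strategies — all
  faithful to the source analysis rather than gaps to be filled.
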