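---
title: "Methods: a Markov cohort model for anti-VEGF cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for anti-VEGF cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ophthCEA)
```

## The model and its assumptions

`ophthCEA` implements a cohort-level state-transition (Markov chain) model
for comparing two intravitreal anti-VEGF strategies, conbercept and
ranibizumab, in three macular diseases: age-related macular degeneration
(AMD), diabetic macular edema (DME), and pathological myopia (PM). The
model's assumptions, all deliberate simplifications:

* **States are BCVA bands.** Vision, measured in ETDRS letters, is binned
  into ordered severity bands (6 for AMD, 5 for DME/PM). Nothing else about
  the patient is tracked — no age, no mortality, no fellow-eye status.
* **One-year cycles, ten-year horizon.** The same annual transition matrix
  is applied every cycle: treatment efficacy, injection frequency and prices
  are all assumed constant over the decade.
* **No death state.** The cohort mass is conserved; QALYs are pure
  quality weights times time, not survival-adjusted.
* **Costs are drug costs by default.** Annual cost is
  `unit_price × injections_per_year + other_annual_cost`, with
  `other_annual_cost = 0` unless the user supplies one (see "Known gaps").

## From letter-change outcomes to a transition matrix

Clinical sources report annual outcomes as letter-change categories: gain or
lose 15 letters (AMD, DME) plus gain or lose 30 (PM), or no change. The
engine maps these uniformly to band shifts: ±15 letters ⇝ one band, ±30 ⇝
two bands — even though AMD's bands are 10–20 letters wide. States are the
only granularity the outcome data support; a letter-level model would be
spurious precision.

**Boundary folding.** A shift off the end of the ladder folds into the
nearest feasible state: improvement from the best band adds to its stay
probability, worsening from blindness likewise, and a two-band improvement
from the second-best band becomes a one-band improvement. This conserves
probability mass exactly (each row of the matrix sums to the outcome
distribution's mass, i.e. 1 after normalization). The original model
diagrams that would settle the intended arrows are not available as data, so
folding is this package's own design choice; the main alternative reading —
blindness as an absorbing state — is available via
`build_transition_matrix(..., blindness_absorbing = TRUE)` and is *off* by
default, because the outcome categories are reported unconditionally on
state.

Rounded source probabilities can miss 1 by a residue (the PM ranibizumab
column sums to 0.9998); `normalize_outcomes()` divides through and warns.
Residues beyond ±0.01 are treated as data errors, not rounding.

## Utilities and unit conversions

DME/PM band utilities come from the linear valuation
`u = 0.828 − 0.359 × logMAR`. The letters↔logMAR conversion
`logMAR = (85 − letters)/50` is the standard ETDRS chart relation; it is
adopted here because it reproduces every published formula-derived utility
exactly when each band is valued at its upper letter bound (75, 60, 45, 30),
with the open blindness band anchored at 15 letters, continuing the
15-letter (0.3 logMAR) spacing. Both the upper-bound anchoring and the
blindness anchor are inferences from exact numeric agreement, not stated
intent. AMD utilities are literature values used as-is
(0.9, 0.85, 0.81, 0.57, 0.52, 0.4).

The formula's [0, 1] clamp in `utility_from_logmar()` only acts outside
logMAR ≈ 2.3, far beyond the model's range.

Baseline shares: the best-vision state starts empty (share 0) but remains
reachable — patients can improve into it. The AMD baseline column sums to
0.9999 in the source; shares are renormalized proportionally with a warning.

## Discounting and QALY accrual

Both streams discount at 3.5 %/year by default. Two conventions are
explicit switches rather than silent choices:

* `discount_first_cycle` (default `FALSE`): cycle *t* contributes
  `value/(1+r)^t` with *t* = 0 for the first year (annuity-due). The source
  is silent on timing; annuity-due is the common spreadsheet-model default.
* `half_cycle_correction` (default `FALSE`): per-cycle QALY uses
  start-of-cycle occupancy; the correction averages start and end occupancy.
  No correction is mentioned in the source, so it defaults off.

## Decision statistics

`compare_arms()` reports ΔC, ΔE, per-arm CERs, the ICER (undefined at
ΔE = 0 — division by zero must not silently propagate; dominance is then
decided on cost alone), a dominance class (`a_dominant` / `b_dominant` /
`trade_off`), and a cost-effectiveness decision. **Decisions always route
through net monetary benefit** (`NMB = λE − C`): a negative ICER is
ambiguous (it arises for both dominant and dominated strategies), and for a
south-west comparison (cheaper, less effective) the ICER must *exceed* λ to
favor the cheaper arm. This matters for AMD: the published analysis reads
its south-west ICER of 66,669 RMB/QALY as "below the threshold, hence
cost-effective", but under NMB logic the 44,335 RMB saved does not
compensate 0.665 forgone QALYs valued at 212,676 RMB each
(0.665 × 212,676 ≈ 141,430 RMB). The package reports the NMB decision and
does not reproduce the directional reading as a computed claim; the printed
ICER itself *is* reproduced exactly from the printed inputs. Exact NMB ties
report "not cost-effective" with a warning.

The willingness-to-pay threshold is `gdp_per_capita × multiplier`, default
70,892 × 3 = 212,676 RMB/QALY (2019 Chinese per-capita GDP, the usual
3×-GDP ceiling for developing economies).

## Sensitivity analysis

* **Deterministic sweeps** re-run the full comparison per swept value
  (`one_way_sweep`) or per grid cell (`two_way_sweep`), over unit prices or
  injection counts, as absolute values or relative fluctuations (the ±5 %
  / ±10 % price analysis). `negotiated_price_scenario()` applies the
  2020–2021 negotiated prices (4,160 / 3,950 RMB).
* **PSA** randomizes *only costs*, exactly as the source describes: each
  arm's total discounted cost is drawn from a gamma with mean equal to the
  deterministic total, shape `1/cv²`, scale `mean·cv²`. No cost variance is
  published, so the coefficient of variation is a required, visible
  parameter (default 0.2 — a moderate uncertainty typical for cost
  parameters in published CEAs; sensitivity of the CEAC to this choice is
  part of any honest report). Utilities and transitions stay fixed; a
  broader PSA would be a different model and is deliberately not implemented.
* **CEAC** points are the empirical fraction of iterations with
  `NMB_a > NMB_b`; ties count against arm a; the two arms' curves sum to 1
  at every threshold. One seeded generator drives the run; the two arms'
  draws are separate, independent vectors from that stream, making arm costs
  uncorrelated (the source says nothing about correlation).

## The synthetic-scenario generator

`generate_scenario()` emulates the *statistical shape* of the real parameter
tables: baseline shares and outcome probabilities from flat (symmetric,
concentration-1) Dirichlet draws — maximally uninformative, which stresses
the boundary-folding logic with large off-diagonal mass; utilities sampled
uniformly then sorted decreasing (simpler and unbiased over the constrained
region, versus sequential constrained sampling); prices and injection counts
uniform in user ranges bracketing the real values (1,000–10,000 RMB,
1–12/yr). It does **not** emulate real data's features beyond structure: no
correlation between efficacy and price, no realistic concentration of
probability on "no change", no trial noise. A green property test therefore
establishes structural correctness (conservation, stochasticity, oracle
agreement, validator consistency) — not clinical plausibility.

`closed_form_qaly_oracle()` is the engine-independent check: under identity
transitions the discounted QALY total is
`(baseline · utilities) × Σ (1+r)^−t`, which the cohort engine must match to
1e-10.

## Numerical choices

* Validation tolerances: probability vectors must sum to 1 within 5e-4
  before renormalization (rounding residue scale) and within 1e-12 after;
  occupancy conservation is checked at 1e-10 over 10-cycle runs.
* Full-precision arithmetic throughout; 3-decimal rounding only in CSV
  output, mirroring the published tables. JSON reports keep full precision.
* Scenario configs are JSON (via `jsonlite`) rather than YAML: no YAML
  parser is part of the package's dependency budget, and JSON round-trips
  doubles losslessly with `digits = NA`.

## Known limitations

* The published 10-year totals (e.g. 285,285.597 RMB / 7.825 QALYs for AMD
  conbercept) are **not reproducible** from published inputs: the printed
  drug-cost annuity is 5,550 × 4.8 × 8.60769 ≈ 229,309 RMB, so the totals
  include unstated non-drug cost components, and the QALY totals embed
  unstated boundary/discount conventions. `other_annual_cost` exists so
  users can calibrate, but no value is invented as a default. The package's
  acceptance surface is therefore the published *arithmetic identities*
  (ΔC, CERs, the AMD ICER) and the exactly-stated formulas (utility ladder,
  WTP threshold), all of which it reproduces.
* No treatment switching, discontinuation, mortality, adverse-event or
  indirect costs; no comparison with aflibercept/bevacizumab.
* PM injection counts are first-year numbers applied to all ten years,
  matching the source's stated constant-injection assumption.
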