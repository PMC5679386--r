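---
title: "Methods: lifetime cohort modelling of adjuvant breast radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime cohort modelling of adjuvant breast radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radcea)
```

## The decision problem

After breast-conserving surgery for early-stage breast cancer, adjuvant
radiation can be delivered in a single intraoperative session (IORT) or as
roughly six weeks of fractionated whole-breast external-beam therapy (EBRT).
The two techniques differ in up-front cost, in acute complication burden, and
— the distinctive part of this model — in the radiation dose delivered to
organs at risk, which drives late complications (major coronary events,
lung cancer, contralateral breast cancer) a decade or more after treatment.
`radcea` evaluates both strategies over the patient's remaining lifetime with
an annual-cycle Markov cohort model and compares them on discounted cost,
QALYs, dominance, cost per QALY and net monetary benefit (NMB) at a
willingness-to-pay threshold.

## Model structure and assumptions

Each strategy is a set of health states (well, local/regional recurrence,
metastatic recurrence, comorbid illness, a pooled late-complication state,
dead) plus transition rules. Key structural choices:

- **Cycle length is one year.** Published "cycle lengths" per condition are
  interpreted as *dwell durations* — years of remaining life in that
  condition — not as alternative cycle widths. A state with bounded dwell
  `D` is expanded into `ceiling(D)` tunnel copies; a fractional final year
  carries weight `D - floor(D)` on utility, annual cost and life-years, so an
  entrant's expected dwell equals `D` exactly.
- **Rewards accrue to start-of-cycle occupancy; transitions fire at cycle
  end.** A half-cycle correction flag instead averages start- and
  end-of-cycle occupancy; it is off by default because the committed
  reference model reproduces the published totals without it.
- **Discount year index counts from 0** at the treatment year, so acute-phase
  costs are undiscounted. Costs and utilities have separate rates.
- **The acute phase is an expected one-time adjustment at cycle 0**
  (procedure cost, complication probability × complication cost, complication
  probability × disutility), not a separate state: no acute-state duration is
  published, and an expected-value adjustment is exact for a cohort model.
- **Comorbid death is an annual competing risk** from the well state into a
  comorbid-illness state with a 6.05-year dwell (midpoint of the published
  4.2–7.9-year range; the range itself is left to sensitivity sweeps). The
  alternative — a one-time branch — is expressible with a
  `cumulative_over_window` rule, but the competing-risk form is the default
  because it keeps the well-state exit mass interpretable year by year.
- **The run extends until dwell chains drain.** `run_cohort(cycles = "auto")`
  runs `horizon` cycles plus the sum of bounded dwells, so a patient entering
  a dwell-limited state late still accrues its full residual life expectancy.
  This matters for threshold analysis: the metastatic life expectancy can
  only flip the preferred strategy if metastatic years beyond the well-state
  horizon are actually accrued. `horizon` itself is the complication-free
  life expectancy (23 years): it sets the well-state dwell and the default
  end of transition windows.

### Pooled events and probability conversion

Cumulative probabilities over a window are converted to constant annual
probabilities by `1 - (1 - p)^(1/W)`. The published 10-year figures (23%
IORT, 25.4% EBRT) pool recurrence *and* death, so a single scalar must feed
several destination states. Storing per-destination cumulative values and
annualizing each separately would not recompound to the printed total;
instead a strategy declares a *pooled event* `{value, window}` and
`pooled_share` rules split the annual hazard in log-survival space
(`a_i = 1 - (1-p)^(w_i/W)` with shares `w_i` summing to 1), which recompounds
exactly and keeps the published figure addressable as one config scalar for
sweeps and threshold searches.

### Dose weighting

Late-complication risk is linear in organ dose with no threshold:
`p_i = min(1, k_i × d_i)` per complication type, with the pooled total
clamped to 1 (the clamp matters only in pathological sensitivity sweeps).
The per-Gy coefficients are configuration values; the defaults are calibrated
to two published anchors — a pooled IORT late-complication probability of
0.31% and a 15× pooled EBRT/IORT risk ratio — with the heart coefficient
carrying most of the IORT total and the contralateral-breast coefficient
solved from the EBRT total. The per-complication incidences then weight each
component's life expectancy, initial cost, ongoing annual cost and
last-year-of-life cost into a single pooled state; component life
expectancies (16.2, 10.0 and a solved ≈15.1 years) were chosen once so the
pooled dwell equals the published 16 (IORT) and 14 (EBRT) years. The pooled
state's last-year cost is charged at dwell exit, its initial cost on entry.
The whole derivation runs inside the evaluation pipeline on every call, so
sweeping a dose or coefficient propagates; a per-strategy
`ltc.probability_override` scalar (absent by default, baseline equal to the
derived total) exists so the pooled probability itself can be swept directly.

## Parameters that matter

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `wtp` | USD/QALY | 50,000 | conventional US threshold |
| `discount_rate_cost` | /year | 0.03 | standard practice |
| `discount_rate_utility` | /year | 0.03 (0 in the reference config; see below) | |
| `horizon` | years | 23 | complication-free life expectancy |
| `half_cycle_correction` | flag | off | see above |
| pooled event probability | 10-year cumulative | 0.23 / 0.254 | trial-derived anchors |
| organ doses | Gy | (1.25, 0.03, 0) / (5, 3.8, 1.1) | mean heart / ipsilateral lung / contralateral breast |
| well utility | — | 0.92 | published anchor |

## The discounting reconciliation in the reference configuration

With a 3%/year utility discount and a 23-year horizon, the discounted QALY
ceiling is `sum_{t=0}^{22} 1.03^{-t} = 16.93` even at utility 1.0 — below
both published totals (17.86 and 17.06). Those totals are therefore only
reachable with *undiscounted* utilities (undiscounted ceiling
23 × 0.92 = 21.16), and the committed reference configuration sets
`discount_rate_utility = 0` while keeping costs at 3%/year. The engine
supports any rate; this is a property of the reference parameterization, not
of the package.

## What the reference configuration is, and is not

Every published parameter is embedded verbatim. Everything else — state
costs, non-well utilities, the event split across local/metastatic/death
(0.20/0.30/0.50 on the hazard scale), the comorbid annual risk (0.004),
acute-phase parameters and the component cost schedules — is **synthetic
calibration**: fitted once, offline, by coarse search plus local refinement
so both strategies' lifetime totals land within 5% of the published
$53,179 / 17.86 QALY and $63,828 / 17.06 QALY, then frozen in code. Two
consequences are worth stating plainly:

- The calibrated model reproduces the published *totals*, dominance ordering
  and NMB preference, and the *direction* of every published sensitivity
  threshold (EBRT event probability must fall below its baseline, IORT event
  and late-complication probabilities must rise above theirs, metastatic life
  expectancy must rise far above baseline, and the well-utility margin
  shrinks monotonically toward the degenerate flip at 0). The *numeric*
  threshold values depend on the unpublished cost schedule and are not
  calibration targets.
- Passing tests on this configuration shows the machinery is faithful to the
  published anchors under one coherent completion of the missing parameters;
  it does not validate those synthetic values against real data.

The seeded random-model generator (`random_model()`) exercises the engine's
invariants (occupancy conservation, validity by construction, finite totals)
across arbitrary topologies; it emulates structural variety, not clinical
realism — utilities uniform on [0, 1] and log-uniform costs are deliberately
unrealistic stress inputs.

## Numerical choices

- Occupancy conservation is checked every cycle at 1e-9 (transition rows sum
  to 1 by construction; the check guards against structural bugs).
- Exit probability mass from any state in any window regime may not exceed
  1 + 1e-12; violations are validation errors (or runtime errors naming the
  state and cycle if they arise mid-run).
- Threshold search scans 64 equally spaced points, requires at most one sign
  change (several raise an ambiguity error listing the brackets), and bisects
  to a default tolerance of `1e-6 × (high − low)` — far below any reporting
  precision; the reference-model searches in the test-suite use coarser
  explicit tolerances (1e-3, or 1 year for the metastatic-dwell search) since
  only the flip direction is meaningful there.
- `cumulative_to_annual(1, W)` is a domain error (infinite hazard);
  `p_cum = 0` maps to 0.
- Degenerate weighted means (all-zero incidence weights) are errors rather
  than NaN; a zero derived late-complication probability simply omits the
  pooled state.
- Ties in dominance classification: equality on both axes is a tie; weak
  equality on one axis with strict improvement on the other counts as
  dominance.

## Problem sizes in the test-suite

Property suites run 100 seeded random models for conservation, 50 toy
parameterizations against the geometric closed form (1e-10 agreement), 20
constant-probability models against an independent matrix-power oracle
(1e-10), 1,000 random pairs against a sign-pattern dominance oracle, and a
10,000-point analytic grid against the bisection root. These sizes give each
property broad coverage while keeping the whole suite under a minute on one
CPU.

## Known limitations

- Cohort fractions only; no individual-level microsimulation.
- One-way (deterministic) sensitivity analysis only; no probabilistic
  sensitivity analysis, acceptability curves or EVPI.
- Doses are inputs; no dosimetry from treatment plans.
- Currency is undated USD; price-level adjustment is pre-processing outside
  the package.
- The late-complication state pools its components into one dwell/cost/
  utility profile; component-specific trajectories after onset are not
  modelled.
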