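# radcea

Lifetime Markov cohort cost-effectiveness analysis for adjuvant breast
radiotherapy: intraoperative radiation therapy (IORT, a single intraoperative
session) versus six weeks of whole-breast external-beam radiation therapy
(EBRT) after breast-conserving surgery. The package is aimed at health
economists and radiation oncology researchers who want a tested, config-driven
re-implementation of this comparison — including the downstream consequences
of radiation dose to the heart, ipsilateral lung and contralateral breast —
rather than a point-and-click decision-tree model.

## The model

A cohort of patients enters a well ("complication-free") state after surgery
plus radiotherapy and transitions between health states in annual cycles:

- **Well** — complication-free, utility 0.92, life expectancy 23 years;
- **Local/regional recurrence** (10-year dwell), **metastatic recurrence**
  (5.625-year dwell) and death, entered through a pooled 10-year cumulative
  event probability (23% IORT, 25.4% EBRT) split across destinations on the
  hazard scale so the pooled figure recompounds exactly;
- **Comorbid illness** (6.05-year dwell) as an annual competing risk;
- **Late radiation complication** — a single pooled state derived from organ
  doses. Excess risk is linear in dose, `p_i = min(1, k_i · d_i)` per
  complication type (major coronary events, lung cancer, contralateral breast
  cancer); the per-complication incidences then weight component life
  expectancies and costs into one state (16-year dwell for IORT, 14 for EBRT,
  entered after year 10);
- **Dead** — absorbing.

Dwell-limited states are expanded into tunnel-state chains (fractional final
years carry fractional reward weight). Each cycle accrues
`occupancy × utility / (1+r_u)^t` QALYs and `occupancy × cost / (1+r_c)^t`
dollars (plus one-time entry/exit costs on moving fractions); cycle 0 adds
the acute phase. Strategies are compared by dominance, cost per QALY, ICER
where meaningful, and net monetary benefit

```
NMB = QALYs × WTP − cost,        WTP = $50,000/QALY
```

One-way sensitivity analysis sweeps any numeric scalar in the configuration
by dotted path, ranks parameters tornado-style by NMB spread, and finds the
parameter value at which the NMB-preferred strategy flips (64-point bracket
scan, then bisection).

## Worked example

```r
library(radcea)

cfg <- iort_ebrt_fixture()      # committed reference configuration
res <- evaluate_config(cfg)     # dose weighting -> cohort engine -> CEA
res$cea
#> <radcea_cea> WTP = $50,000/QALY, preferred by NMB: IORT
#> # A tibble: 2 × 5
#>   strategy direct_cost qalys cost_per_qaly    nmb
#>   <chr>          <dbl> <dbl>         <dbl>  <dbl>
#> 1 IORT           53188  17.5          3039 821976
#> 2 EBRT           63820  17.0          3746 788055
```

IORT is *dominant*: cheaper by $10,632 over the patient's remaining lifetime
and better by 0.47 QALYs, so it also has the higher net monetary benefit at
$50,000/QALY. The per-patient saving scales to the population level:

```r
budget_impact(annual_cases = 60000, per_patient_saving = 10632,
              per_patient_indirect_delta = 1520)
#> # A tibble: 1 × 3
#>   annual_cases direct_total indirect_total
#>          <dbl>        <dbl>          <dbl>
#> 1        60000    637920000       91200000
```

Threshold analysis asks how far a parameter must move before the preference
flips — here, how low the EBRT 10-year event probability would have to fall
(baseline 25.4%):

```r
find_threshold(cfg, "strategies.EBRT.pooled_events.recurrence_death.value",
               bounds = c(0.02, 0.6), tolerance = 1e-3)
#> # A tibble: 1 × 5
#>   param_path                  threshold tolerance preferred_below preferred_above
#> 1 strategies.EBRT.pooled_ev…      0.206     0.001 EBRT            IORT
```

`one_way_sweep()` and `tornado()` return tibbles with `autoplot()` methods;
`run_analysis(cfg, "out/")` writes the full report bundle (comparison table,
trajectories, tornado/threshold tables, run log).

State costs and non-well utilities in the reference configuration are
synthetic calibration values (the underlying full parameter tables are not
published); every parameter that *is* published — dwell times, the 0.92
utility, event probabilities, organ doses, the 0.31% IORT late-complication
probability, discounting and WTP — is embedded verbatim. See the methods
vignette (`vignettes/radcea-methods.Rmd`) for the calibration and the
discounting reconciliation.

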