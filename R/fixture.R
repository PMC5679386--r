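# Reference IORT-vs-EBRT configuration.
#
# Published anchors embedded verbatim: 23-year complication-free life
# expectancy; dwell limits 10 (local/regional recurrence), 5.625 (metastatic),
# 16/14 (pooled late complication, IORT/EBRT), 6.05 (midpoint of the 4.2-7.9
# comorbid-death range); well-state utility 0.92; 10-year cumulative
# recurrence/death probabilities 0.23 (IORT) and 0.254 (EBRT); pooled IORT
# late-complication probability 0.0031 with a 15x EBRT/IORT pooled ratio;
# organ doses (5, 3.8, 1.1) Gy for EBRT and (1.25, 0.03, 0) Gy for IORT;
# WTP $50,000/QALY; 3%/year cost discounting.
#
# Everything else (state costs, non-well utilities, event split shares,
# acute-phase parameters, component costs) is NOT published: these are
# SYNTHETIC calibration values, fitted once offline so that the engine's
# lifetime totals fall within 5% of the published $53,179 / 17.86 QALY (IORT)
# and $63,828 / 17.06 QALY (EBRT). Utilities are left undiscounted in this
# fixture: the published QALY totals exceed the 3%-discounted ceiling
# (sum_{t<23} 1.03^-t = 16.93 even at utility 1), so they can only be
# reproduced without utility discounting; see the methods vignette.

fixture_constants <- function() {
  # per-Gy excess late-complication probabilities (calibrated to the 0.31%
  # IORT anchor and the 15x pooled EBRT/IORT ratio)
  c_mce <- 0.0024
  c_lung <- 0.01 / 3
  iort_total <- 0.0031          # = c_mce*1.25 + c_lung*0.03
  ebrt_total <- 15 * iort_total # "over 15 times" pooled ratio anchor
  c_breast <- (ebrt_total - c_mce * 5 - c_lung * 3.8) / 1.1
  # component life expectancies solved so the incidence-weighted pooled dwell
  # equals the published 16 (IORT) and 14 (EBRT) years
  le_mce <- 16.2
  le_lung <- (iort_total * 16 - c_mce * 1.25 * le_mce) / (c_lung * 0.03)
  le_breast <- (ebrt_total * 14 - c_mce * 5 * le_mce - c_lung * 3.8 * le_lung) /
    (c_breast * 1.1)
  list(
    coefficients = risk_coefficients(
      mce = c_mce, lung_cancer = c_lung, contralateral_breast_cancer = c_breast
    ),
    life_expectancies = c(mce = le_mce, lung_cancer = le_lung,
                          contralateral_breast = le_breast),
    # SYNTHETIC (calibration): costs per component
    components = list(
      complication_component("mce", life_expectancy = le_mce,
                             initial_cost = 42000, ongoing_annual_cost = 5200,
                             last_year_cost = 52000),
      complication_component("lung_cancer", life_expectancy = le_lung,
                             initial_cost = 75000, ongoing_annual_cost = 12000,
                             last_year_cost = 90000),
      complication_component("contralateral_breast_cancer",
                             life_expectancy = le_breast,
                             initial_cost = 48000, ongoing_annual_cost = 8000,
                             last_year_cost = 65000)
    ),
    # SYNTHETIC (calibration): event split, comorbid risk, utilities, costs
    event_shares = c(local = 0.20, metastatic = 0.30, death = 0.50),
    p_comorbid = 0.0040,
    u_local = 0.72, u_metastatic = 0.55, u_comorbid = 0.70, u_ltc = 0.35,
    well_cost = 1000, well_exit_cost = 28000,
    local_entry = 26000, local_cost = 3200, local_exit = 32000,
    met_entry = 42000, met_cost = 12500, met_exit = 42000,
    com_entry = 6000, com_cost = 6500, com_exit = 30000,
    acute = list(
      IORT = acute_phase(procedure_cost = 14100,
                         complication_probability = 0.12,
                         complication_cost = 3200,
                         complication_disutility = 0.05),
      EBRT = acute_phase(procedure_cost = 20300,
                         complication_probability = 0.30,
                         complication_cost = 3800,
                         complication_disutility = 0.38)
    )
  )
}

fixture_strategy <- function(name, k, p_event_10y, dose) {
  sh <- k$event_shares
  states <- list(
    health_state("Well", annual_cost = k$well_cost, utility = 0.92,
                 max_dwell = 23, on_dwell_exit = "Dead",
                 exit_cost = k$well_exit_cost),
    health_state("LocalRegional", annual_cost = k$local_cost,
                 entry_cost = k$local_entry, utility = k$u_local,
                 max_dwell = 10, on_dwell_exit = "Dead",
                 exit_cost = k$local_exit),
    health_state("Metastatic", annual_cost = k$met_cost,
                 entry_cost = k$met_entry, utility = k$u_metastatic,
                 max_dwell = 5.625, on_dwell_exit = "Dead",
                 exit_cost = k$met_exit),
    health_state("ComorbidIllness", annual_cost = k$com_cost,
                 entry_cost = k$com_entry, utility = k$u_comorbid,
                 max_dwell = 6.05, on_dwell_exit = "Dead",
                 exit_cost = k$com_exit),
    health_state("Dead", utility = 0)
  )
  transitions <- list(
    transition_rule("Well", "LocalRegional", "pooled_share",
                    value = unname(sh["local"]), pool = "recurrence_death"),
    transition_rule("Well", "Metastatic", "pooled_share",
                    value = unname(sh["metastatic"]), pool = "recurrence_death"),
    transition_rule("Well", "Dead", "pooled_share",
                    value = unname(sh["death"]), pool = "recurrence_death"),
    transition_rule("Well", "ComorbidIllness", "annual_probability",
                    value = k$p_comorbid)
  )
  strategy_model(
    name = name,
    acute = k$acute[[name]],
    states = states,
    transitions = transitions,
    initial_state = "Well",
    dose = dose,
    pooled_events = list(
      recurrence_death = list(value = p_event_10y, window_start = 0, window_end = 10)
    ),
    ltc = list(window_start = 10, window_end = 23, utility = k$u_ltc)
  )
}

#' Reference IORT-vs-EBRT model configuration
#'
#' The committed two-strategy breast-radiotherapy model: intraoperative
#' radiotherapy (IORT) versus six weeks of whole-breast external-beam
#' radiotherapy (EBRT) after breast-conserving surgery, followed over the
#' patient's remaining lifetime. All published anchors (dwell limits, the
#' 0.92 well utility, 10-year cumulative event probabilities 23%/25.4%,
#' organ doses, the 0.31% IORT late-complication probability, $50,000/QALY
#' WTP, 3%/year cost discounting, 23-year horizon) are embedded verbatim;
#' the remaining state costs, non-well utilities, event-split shares and
#' acute-phase parameters are synthetic calibration values, fitted once so
#' lifetime totals land within 5% of the published $53,179 / 17.86 QALY
#' (IORT) and $63,828 / 17.06 QALY (EBRT). Utilities are undiscounted in
#' this fixture (see the methods vignette for the arithmetic that forces
#' this); costs are discounted at 3%/year.
#'
#' @return A validated `radcea_config` with strategies `IORT` and `EBRT`.
#' @export
#' @examples
#' cfg <- iort_ebrt_fixture()
#' evaluate_config(cfg)$cea
iort_ebrt_fixture <- function() {
  k <- fixture_constants()
  radcea_config(
    economics = economic_settings(
      wtp = 50000,
      discount_rate_cost = 0.03,
      discount_rate_utility = 0,  # see fixture header note
      horizon = 23,
      half_cycle_correction = FALSE
    ),
    strategies = list(
      fixture_strategy("IORT", k, p_event_10y = 0.23,
                       dose_profile(heart_gy = 1.25, ipsilateral_lung_gy = 0.03,
                                    contralateral_breast_gy = 0)),
      fixture_strategy("EBRT", k, p_event_10y = 0.254,
                       dose_profile(heart_gy = 5, ipsilateral_lung_gy = 3.8,
                                    contralateral_breast_gy = 1.1))
    ),
    coefficients = k$coefficients,
    components = k$components
  )
}

#' Default sensitivity ranges for the reference configuration
#'
#' The one-way ranges used for the fixture's tornado and threshold analyses:
#' the well-state utility, both strategies' pooled 10-year event
#' probabilities, the metastatic life expectancy, and the IORT
#' late-complication probability (addressed through its override scalar,
#' whose baseline equals the dose-derived 0.0031).
#'
#' @return Named list of [sensitivity_range()]s.
#' @export
fixture_sensitivity_ranges <- function() {
  list(
    well_utility = sensitivity_range(
      "strategies.*.states.Well.utility", 0, 0.92),
    iort_event_probability = sensitivity_range(
      "strategies.IORT.pooled_events.recurrence_death.value", 0.05, 0.6),
    ebrt_event_probability = sensitivity_range(
      "strategies.EBRT.pooled_events.recurrence_death.value", 0.05, 0.6),
    metastatic_life_expectancy = sensitivity_range(
      "strategies.*.states.Metastatic.max_dwell", 1, 300),
    iort_ltc_probability = sensitivity_range(
      "strategies.IORT.ltc.probability_override", 0.0031, 0.30)
  )
}
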