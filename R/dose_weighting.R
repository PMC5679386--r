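# Organ-dose to late-complication mapping: linear no-threshold excess
# probability per Gy over the late (> 10 year) window, one coefficient per
# complication type (major coronary events, lung cancer, contralateral
# breast cancer).

complication_organs <- c(
  mce = "heart_gy",
  lung_cancer = "ipsilateral_lung_gy",
  contralateral_breast_cancer = "contralateral_breast_gy"
)

#' Organ radiation dose profile
#'
#' Mean absorbed doses (Gy) delivered to the organs at risk by one strategy.
#'
#' @param heart_gy,ipsilateral_lung_gy,contralateral_breast_gy Mean organ
#'   doses in gray.
#' @return A list of class `radcea_dose`.
#' @export
dose_profile <- function(heart_gy = 0, ipsilateral_lung_gy = 0,
                         contralateral_breast_gy = 0) {
  d <- list(heart_gy = heart_gy, ipsilateral_lung_gy = ipsilateral_lung_gy,
            contralateral_breast_gy = contralateral_breast_gy)
  if (!all(vapply(d, is_nonneg, logical(1)))) {
    abort("doses must be non-negative Gy", class = "radcea_validation_error")
  }
  structure(d, class = "radcea_dose")
}

#' Per-Gy excess late-complication risk coefficients
#'
#' @param mce,lung_cancer,contralateral_breast_cancer Excess probability per
#'   Gy over the late complication window for each complication type.
#' @return Named numeric vector.
#' @export
risk_coefficients <- function(mce = 0, lung_cancer = 0,
                              contralateral_breast_cancer = 0) {
  k <- c(mce = mce, lung_cancer = lung_cancer,
         contralateral_breast_cancer = contralateral_breast_cancer)
  if (any(k < 0)) {
    abort("risk coefficients must be >= 0", class = "radcea_validation_error")
  }
  k
}

#' Late-complication component (cost and survival inputs)
#'
#' One complication type contributing to the pooled late-complication state.
#'
#' @param name Complication identifier (must match a coefficient name).
#' @param life_expectancy Years lived after onset.
#' @param initial_cost,ongoing_annual_cost,last_year_cost USD: one-time at
#'   onset, per year thereafter, and in the final year of life.
#' @return A list of class `radcea_component`.
#' @export
complication_component <- function(name, life_expectancy, initial_cost = 0,
                                   ongoing_annual_cost = 0, last_year_cost = 0) {
  vals <- c(life_expectancy, initial_cost, ongoing_annual_cost, last_year_cost)
  if (any(vals < 0)) {
    abort("component values must be >= 0", class = "radcea_validation_error")
  }
  structure(
    list(name = name, life_expectancy = life_expectancy,
         initial_cost = initial_cost,
         ongoing_annual_cost = ongoing_annual_cost,
         last_year_cost = last_year_cost),
    class = "radcea_component"
  )
}

#' Convert organ doses to late-complication probabilities
#'
#' Applies the linear no-threshold map `p_i = min(1, coeff_i * dose_i)` per
#' complication type and clamps the pooled total at 1.
#'
#' @param dose A [dose_profile()].
#' @param coeff A [risk_coefficients()] vector.
#' @return A list with `by_complication` (tibble: complication, dose_gy,
#'   probability) and `total` (pooled probability, clamped to 1).
#' @export
#' @examples
#' k <- risk_coefficients(mce = 0.0024, lung_cancer = 0.0033)
#' complication_probabilities(dose_profile(heart_gy = 5, ipsilateral_lung_gy = 3.8), k)
complication_probabilities <- function(dose, coeff) {
  if (any(unlist(dose) < 0) || any(coeff < 0)) {
    abort("doses and coefficients must be >= 0", class = "radcea_validation_error")
  }
  gy <- vapply(complication_organs, function(org) dose[[org]] %||% 0, numeric(1))
  names(gy) <- names(complication_organs)
  k <- vapply(names(complication_organs), function(nm) unname(coeff[nm] %||% 0), numeric(1))
  k[is.na(k)] <- 0
  p <- pmin(1, k * gy)
  list(
    by_complication = tibble(complication = names(complication_organs),
                             dose_gy = unname(gy), probability = unname(p)),
    total = min(1, sum(p))
  )
}

#' Incidence-weighted mean
#'
#' @param values Numeric vector.
#' @param weights Non-negative weights, at least one positive.
#' @return `sum(values * weights) / sum(weights)`.
#' @export
weighted_value <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  if (any(weights < 0)) {
    abort("weights must be >= 0", class = "radcea_validation_error")
  }
  if (sum(weights) <= 0) {
    abort("all weights are zero: weighted mean undefined",
          class = "radcea_degenerate_weights_error")
  }
  sum(values * weights) / sum(weights)
}

#' Pool complication components into one late-complication health state
#'
#' Builds the single long-term-complication state whose dwell is the
#' incidence-weighted life expectancy, entry cost the weighted initial cost,
#' annual cost the weighted ongoing cost, and exit cost the weighted
#' last-year-of-life cost (charged at dwell exit).
#'
#' @param components List of [complication_component()]s.
#' @param probabilities Result of [complication_probabilities()] (or a named
#'   probability vector covering the same complication set).
#' @param name State name.
#' @param utility Quality-of-life weight of the pooled state.
#' @param on_dwell_exit Successor state (default `"Dead"`).
#' @return A [health_state()].
#' @export
pooled_complication_state <- function(components, probabilities,
                                      name = "LateComplication",
                                      utility = 1, on_dwell_exit = "Dead") {
  if (is.list(probabilities) && !is.null(probabilities$by_complication)) {
    p <- setNames(probabilities$by_complication$probability,
                  probabilities$by_complication$complication)
  } else {
    p <- probabilities
  }
  comp_names <- vapply(components, `[[`, character(1), "name")
  if (!setequal(comp_names, names(p))) {
    abort("complication sets of components and probabilities differ",
          class = "radcea_reference_error")
  }
  w <- unname(p[comp_names])
  le <- vapply(components, `[[`, numeric(1), "life_expectancy")
  health_state(
    name = name,
    annual_cost = weighted_value(vapply(components, `[[`, numeric(1), "ongoing_annual_cost"), w),
    entry_cost = weighted_value(vapply(components, `[[`, numeric(1), "initial_cost"), w),
    utility = utility,
    max_dwell = weighted_value(le, w),
    on_dwell_exit = on_dwell_exit,
    exit_cost = weighted_value(vapply(components, `[[`, numeric(1), "last_year_cost"), w)
  )
}

#' Derive the late-complication state and transition for a strategy
#'
#' Runs the dose-weighting pipeline: organ doses and per-Gy coefficients give
#' per-complication probabilities; these weight the component life
#' expectancies and costs into one pooled state, appended to the strategy
#' together with a cumulative transition from the well (initial) state over
#' the late window. When the strategy carries `ltc$probability_override`, the
#' pooled transition probability is replaced by that scalar (the incidence
#' weighting pattern is unchanged).
#'
#' @param strategy A [strategy_model()] with a `dose` profile.
#' @param config The surrounding `radcea_config` (supplies coefficients,
#'   components and the default window end).
#' @return The strategy with the derived state and transition added; returned
#'   unchanged when it has no dose profile or the config has no coefficients.
#' @export
build_strategy <- function(strategy, config) {
  if (is.null(strategy$dose) || is.null(config$coefficients) ||
      is.null(config$components) || "LateComplication" %in% names(strategy$states)) {
    return(strategy)
  }
  probs <- complication_probabilities(strategy$dose, config$coefficients)
  total <- strategy$ltc$probability_override %||% probs$total
  if (total <= 0) return(strategy)
  ltc <- strategy$ltc %||% list()
  state <- pooled_complication_state(
    config$components, probs,
    name = "LateComplication",
    utility = ltc$utility %||% 1
  )
  ws <- ltc$window_start %||% 10
  we <- ltc$window_end %||% config$economics$horizon
  rule <- transition_rule(
    from_state = ltc$from_state %||% strategy$initial_state,
    to_state = "LateComplication",
    mode = "cumulative_over_window",
    value = total, window_start = ws, window_end = we
  )
  strategy$states[[state$name]] <- state
  strategy$transitions <- c(strategy$transitions, list(rule))
  strategy
}
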