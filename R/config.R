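#' Economic settings for a cost-effectiveness analysis
#'
#' @param wtp Willingness to pay, USD per QALY gained.
#' @param discount_rate_cost Annual discount rate applied to costs, as a
#'   fraction (0.03 = 3%/year).
#' @param discount_rate_utility Annual discount rate applied to utilities.
#' @param horizon Complication-free life expectancy in whole years; sets the
#'   well-state dwell and the default end of transition windows.
#' @param half_cycle_correction Logical; when `TRUE`, per-cycle rewards use
#'   the mean of start- and end-of-cycle occupancy.
#' @return A list of class `radcea_economics`.
#' @export
economic_settings <- function(wtp = 50000,
                              discount_rate_cost = 0.03,
                              discount_rate_utility = 0.03,
                              horizon = 23,
                              half_cycle_correction = FALSE) {
  stopifnot(is_nonneg(wtp))
  if (!is_prob(discount_rate_cost) || !is_prob(discount_rate_utility)) {
    abort("discount rates must lie in [0, 1]", class = "radcea_validation_error")
  }
  if (!is_scalar_num(horizon) || horizon < 1) {
    abort("horizon must be at least 1 year", class = "radcea_validation_error")
  }
  structure(
    list(wtp = wtp,
         discount_rate_cost = discount_rate_cost,
         discount_rate_utility = discount_rate_utility,
         horizon = horizon,
         half_cycle_correction = isTRUE(half_cycle_correction)),
    class = "radcea_economics"
  )
}

#' Health state definition
#'
#' A state of the cohort model. Bounded `max_dwell` states are expanded into
#' tunnel copies by the engine; a non-integer dwell weights the final tunnel
#' year fractionally on utility, annual cost and life-years.
#'
#' @param name State identifier.
#' @param annual_cost USD accrued per year of membership.
#' @param entry_cost USD charged once on entry from another state.
#' @param utility Quality-of-life weight in \[0, 1\].
#' @param max_dwell Maximum years in the state (may be fractional); `Inf`
#'   for unbounded.
#' @param on_dwell_exit Successor state at dwell exhaustion (required iff
#'   `max_dwell` is finite).
#' @param exit_cost USD charged once at dwell exit (e.g. last-year-of-life
#'   care).
#' @return A list of class `radcea_state`.
#' @export
health_state <- function(name, annual_cost = 0, entry_cost = 0, utility = 1,
                         max_dwell = Inf, on_dwell_exit = NULL,
                         exit_cost = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(
    list(name = name, annual_cost = annual_cost, entry_cost = entry_cost,
         utility = utility, max_dwell = max_dwell,
         on_dwell_exit = on_dwell_exit, exit_cost = exit_cost),
    class = "radcea_state"
  )
}

#' Transition rule between health states
#'
#' Three modes are supported:
#' \describe{
#'   \item{annual_probability}{`value` is applied each cycle inside the
#'     (optional) window.}
#'   \item{cumulative_over_window}{`value` is the cumulative probability over
#'     `[window_start, window_end)`, annualized internally via
#'     [cumulative_to_annual()].}
#'   \item{pooled_share}{`value` is this destination's share of a strategy
#'     pooled event (see `pooled_events`); shares split the pooled annual
#'     hazard so that the joint cumulative probability recompounds exactly to
#'     the pooled value.}
#' }
#'
#' @param from_state,to_state State names.
#' @param mode One of `"annual_probability"`, `"cumulative_over_window"`,
#'   `"pooled_share"`.
#' @param value Probability (or share) in \[0, 1\].
#' @param window_start,window_end Cycle window (years); the rule applies for
#'   cycles `window_start <= t < window_end`.
#' @param pool Name of the pooled event (pooled_share mode only).
#' @return A list of class `radcea_transition`.
#' @export
transition_rule <- function(from_state, to_state,
                            mode = c("annual_probability",
                                     "cumulative_over_window",
                                     "pooled_share"),
                            value, window_start = NULL, window_end = NULL,
                            pool = NULL) {
  mode <- match.arg(mode)
  structure(
    list(from_state = from_state, to_state = to_state, mode = mode,
         value = value, window_start = window_start,
         window_end = window_end, pool = pool),
    class = "radcea_transition"
  )
}

#' Acute treatment phase
#'
#' One-time costs and expected disutility of surgery plus radiation delivery,
#' applied at cycle 0 before the cohort enters its steady state.
#'
#' @param procedure_cost USD for the procedure itself.
#' @param complication_probability Probability of an acute complication.
#' @param complication_cost USD to treat an acute complication.
#' @param complication_disutility One-time QALY decrement per complication.
#' @return A list of class `radcea_acute`.
#' @export
acute_phase <- function(procedure_cost = 0, complication_probability = 0,
                        complication_cost = 0, complication_disutility = 0) {
  structure(
    list(procedure_cost = procedure_cost,
         complication_probability = complication_probability,
         complication_cost = complication_cost,
         complication_disutility = complication_disutility),
    class = "radcea_acute"
  )
}

#' One treatment strategy (arm) of the model
#'
#' @param name Strategy identifier (e.g. `"IORT"`).
#' @param acute An [acute_phase()].
#' @param states List of [health_state()]s (a single absorbing `Dead` state
#'   with zero cost and utility is required).
#' @param transitions List of [transition_rule()]s.
#' @param initial_state Name of the state the cohort starts in.
#' @param dose A [dose_profile()] (optional; enables derivation of the
#'   late-complication state from organ doses).
#' @param pooled_events Named list of pooled events, each
#'   `list(value, window_start, window_end)` giving a cumulative probability
#'   over the window that `pooled_share` rules split.
#' @param ltc Late-complication settings:
#'   `list(window_start, window_end, utility, probability_override)`;
#'   `window_end`/`probability_override` may be `NULL`.
#' @return A list of class `radcea_strategy`.
#' @export
strategy_model <- function(name, acute = acute_phase(), states, transitions,
                           initial_state, dose = NULL,
                           pooled_events = list(), ltc = NULL) {
  states <- setNames(states, vapply(states, `[[`, character(1), "name"))
  structure(
    list(name = name, acute = acute, states = states,
         transitions = transitions, initial_state = initial_state,
         dose = dose, pooled_events = pooled_events, ltc = ltc),
    class = "radcea_strategy"
  )
}

#' Assemble a full analysis configuration
#'
#' @param economics An [economic_settings()].
#' @param strategies List of [strategy_model()]s (named by strategy on
#'   assembly).
#' @param coefficients Named per-Gy excess-probability coefficients (see
#'   [risk_coefficients()]); optional.
#' @param components List of late-complication component lists (see
#'   [complication_component()]); optional.
#' @return A list of class `radcea_config`.
#' @export
radcea_config <- function(economics, strategies, coefficients = NULL,
                          components = NULL) {
  strategies <- setNames(strategies,
                         vapply(strategies, `[[`, character(1), "name"))
  structure(
    list(economics = economics, coefficients = coefficients,
         components = components, strategies = strategies),
    class = "radcea_config"
  )
}

# ---- file I/O ---------------------------------------------------------------

# JSON serializers may turn NULL into an empty container; normalize back.
null_if_empty <- function(x) if (is.null(x) || length(x) == 0L) NULL else x

num_or_null <- function(x) {
  x <- null_if_empty(x)
  if (is.null(x)) NULL else as.numeric(x)
}

strategy_from_list <- function(x) {
  states <- lapply(x$states, function(s) {
    health_state(
      name = s$name,
      annual_cost = s$annual_cost %||% 0,
      entry_cost = s$entry_cost %||% 0,
      utility = s$utility %||% 1,
      max_dwell = if (is.null(null_if_empty(s$max_dwell))) Inf else as.numeric(s$max_dwell),
      on_dwell_exit = null_if_empty(s$on_dwell_exit),
      exit_cost = s$exit_cost %||% 0
    )
  })
  transitions <- lapply(x$transitions, function(tr) {
    transition_rule(
      from_state = tr$from_state, to_state = tr$to_state,
      mode = tr$mode %||% "annual_probability", value = tr$value,
      window_start = num_or_null(tr$window_start),
      window_end = num_or_null(tr$window_end),
      pool = null_if_empty(tr$pool)
    )
  })
  ac <- x$acute %||% list()
  strategy_model(
    name = x$name,
    acute = acute_phase(
      procedure_cost = ac$procedure_cost %||% 0,
      complication_probability = ac$complication_probability %||% 0,
      complication_cost = ac$complication_cost %||% 0,
      complication_disutility = ac$complication_disutility %||% 0
    ),
    states = states, transitions = transitions,
    initial_state = x$initial_state,
    dose = if (is.null(x$dose)) NULL else do.call(dose_profile, x$dose),
    pooled_events = x$pooled_events %||% list(),
    ltc = x$ltc
  )
}

config_from_list <- function(x) {
  econ <- x$economics %||% list()
  economics <- economic_settings(
    wtp = econ$wtp %||% 50000,
    discount_rate_cost = econ$discount_rate_cost %||% 0.03,
    discount_rate_utility = econ$discount_rate_utility %||% 0.03,
    horizon = econ$horizon %||% 23,
    half_cycle_correction = econ$half_cycle_correction %||% FALSE
  )
  strategies <- lapply(x$strategies, strategy_from_list)
  coefficients <- if (is.null(x$risk_coefficients)) NULL else
    unlist(x$risk_coefficients)
  components <- if (is.null(x$complication_components)) NULL else
    lapply(x$complication_components, function(cc) do.call(complication_component, cc))
  radcea_config(economics, strategies, coefficients, components)
}

strip_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_class)
    attributes(x) <- list(names = names(x))
  }
  x
}

config_to_list <- function(config) {
  out <- list(
    economics = strip_class(unclass(config$economics)),
    risk_coefficients = if (is.null(config$coefficients)) NULL else
      as.list(config$coefficients),
    complication_components = if (is.null(config$components)) NULL else
      lapply(config$components, strip_class),
    strategies = lapply(unname(config$strategies), strip_class)
  )
  out[!vapply(out, is.null, logical(1))]
}

#' Load and validate a model configuration
#'
#' Reads a JSON (`.json`) or YAML (any other extension) document describing
#' economic settings and two or more strategies, applies defaults
#' (WTP 50,000 USD/QALY, 3%/year discounting), and validates every strategy.
#'
#' @param path Path to the configuration file.
#' @return A validated `radcea_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file '%s' does not exist", path),
          class = "radcea_io_error")
  }
  raw <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) {
      abort(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
            class = "radcea_format_error")
    }
  )
  config <- config_from_list(raw)
  viol <- validate_config(config)
  if (nrow(viol) > 0L) {
    abort(paste0("invalid configuration:\n",
                 paste0("- [", viol$strategy, "] ", viol$element, ": ",
                        viol$message, collapse = "\n")),
          class = "radcea_validation_error")
  }
  config
}

#' Write a configuration as canonical YAML
#'
#' @param config A `radcea_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  txt <- yaml::as.yaml(config_to_list(config), precision = 15L)
  writeLines(txt, path)
  invisible(path)
}
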