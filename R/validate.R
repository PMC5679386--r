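violation <- function(strategy, element, message) {
  tibble(strategy = strategy, element = element, message = message)
}

#' Validate a strategy model
#'
#' Checks every structural invariant of a [strategy_model()] and returns the
#' violations as a tibble rather than raising: utility and probability bounds,
#' non-negative costs, dwell/exit consistency, state-name references, a single
#' absorbing `Dead` state with zero cost and utility, and per-cycle exit
#' probability mass at most 1 from every state in every window regime.
#'
#' @param strategy A [strategy_model()].
#' @param economics An [economic_settings()] (used for default window ends);
#'   optional.
#' @return A tibble with columns `strategy`, `element`, `message`; zero rows
#'   when the model is valid.
#' @export
validate_model <- function(strategy, economics = economic_settings()) {
  v <- list()
  add <- function(element, message) {
    v[[length(v) + 1L]] <<- violation(strategy$name, element, message)
  }
  states <- strategy$states
  state_names <- names(states)
  if (anyDuplicated(state_names)) add("states", "duplicate state names")

  for (s in states) {
    el <- paste0("state:", s$name)
    if (!is_prob(s$utility)) add(el, "utility must lie in [0, 1]")
    if (!is_nonneg(s$annual_cost)) add(el, "annual_cost must be >= 0")
    if (!is_nonneg(s$entry_cost)) add(el, "entry_cost must be >= 0")
    if (!is_nonneg(s$exit_cost)) add(el, "exit_cost must be >= 0")
    if (!is_scalar_num(s$max_dwell) || s$max_dwell <= 0) {
      add(el, "max_dwell must be > 0")
    } else if (is.finite(s$max_dwell)) {
      if (is.null(s$on_dwell_exit)) {
        add(el, "on_dwell_exit required for bounded max_dwell")
      } else if (!s$on_dwell_exit %in% state_names) {
        add(el, sprintf("on_dwell_exit '%s' is not a state", s$on_dwell_exit))
      }
    } else if (!is.null(s$on_dwell_exit)) {
      add(el, "on_dwell_exit only allowed with bounded max_dwell")
    }
  }

  if (!strategy$initial_state %in% state_names) {
    add("initial_state", sprintf("'%s' is not a state", strategy$initial_state))
  }
  dead <- states[["Dead"]]
  if (is.null(dead)) {
    add("states", "model requires an absorbing 'Dead' state")
  } else {
    if (dead$utility != 0) add("state:Dead", "Dead must have utility 0")
    if (dead$annual_cost != 0 || dead$entry_cost != 0 || dead$exit_cost != 0) {
      add("state:Dead", "Dead must have zero costs")
    }
    if (is.finite(dead$max_dwell)) add("state:Dead", "Dead must be unbounded")
  }

  ac <- strategy$acute
  if (!is_prob(ac$complication_probability)) {
    add("acute", "complication_probability must lie in [0, 1]")
  }
  if (!is_nonneg(ac$procedure_cost) || !is_nonneg(ac$complication_cost) ||
      !is_nonneg(ac$complication_disutility)) {
    add("acute", "acute costs and disutility must be >= 0")
  }

  for (nm in names(strategy$pooled_events)) {
    pool <- strategy$pooled_events[[nm]]
    el <- paste0("pooled_event:", nm)
    if (!is.numeric(pool$value) || pool$value < 0 || pool$value >= 1) {
      add(el, "pooled cumulative probability must lie in [0, 1)")
    }
    ws <- pool$window_start %||% 0
    we <- pool$window_end %||% Inf
    if (is.finite(we) && we <= ws) add(el, "window must satisfy window_end > window_start")
  }

  ok_refs <- TRUE
  for (i in seq_along(strategy$transitions)) {
    tr <- strategy$transitions[[i]]
    el <- sprintf("transition:%d(%s->%s)", i, tr$from_state, tr$to_state)
    if (!is_prob(tr$value)) add(el, "value must lie in [0, 1]")
    for (endpoint in c(tr$from_state, tr$to_state)) {
      if (!endpoint %in% state_names) {
        add(el, sprintf("references unknown state '%s'", endpoint))
        ok_refs <- FALSE
      }
    }
    if (identical(tr$from_state, "Dead")) add(el, "no transitions out of Dead")
    if (tr$mode == "cumulative_over_window") {
      ws <- tr$window_start %||% 0
      we <- tr$window_end %||% economics$horizon
      if (we <= ws) add(el, "window must satisfy window_end > window_start")
      if (is_prob(tr$value) && tr$value >= 1) add(el, "cumulative value must be < 1")
    }
    if (tr$mode == "pooled_share" &&
        (is.null(tr$pool) || !tr$pool %in% names(strategy$pooled_events))) {
      add(el, sprintf("references unknown pooled event '%s'", tr$pool %||% "<missing>"))
      ok_refs <- FALSE
    }
  }

  if (!is.null(strategy$dose)) {
    d <- strategy$dose
    if (!all(vapply(d, is_nonneg, logical(1)))) add("dose", "doses must be >= 0 Gy")
  }
  if (!is.null(strategy$ltc)) {
    if (!is_prob(strategy$ltc$utility %||% 1)) {
      add("ltc", "late-complication utility must lie in [0, 1]")
    }
    po <- strategy$ltc$probability_override
    if (!is.null(po) && !is_prob(po)) add("ltc", "probability_override must lie in [0, 1]")
  }

  # per-regime exit probability mass (only meaningful if references resolve)
  if (ok_refs && length(v) == 0L) {
    hz <- tryCatch(annual_hazards(strategy, horizon = economics$horizon),
                   error = function(e) NULL)
    if (!is.null(hz) && nrow(hz) > 0L) {
      breaks <- sort(unique(c(0, hz$window_start, hz$window_end[is.finite(hz$window_end)])))
      for (b in breaks) {
        active <- hz[hz$window_start <= b & b < hz$window_end, , drop = FALSE]
        mass <- tapply(active$annual_p, active$from, sum)
        for (nm in names(mass)) {
          if (mass[[nm]] > 1 + 1e-12) {
            add(paste0("state:", nm),
                sprintf("annualized exit probabilities sum to %.4f (> 1) from cycle %g",
                        mass[[nm]], b))
          }
        }
      }
    }
  }

  if (length(v) == 0L) {
    tibble(strategy = character(0), element = character(0), message = character(0))
  } else {
    dplyr::bind_rows(v)
  }
}

#' Validate a full configuration
#'
#' Runs [validate_model()] on every strategy (after late-complication
#' derivation when dose data are present) and checks cross-strategy fields.
#'
#' @param config A `radcea_config`.
#' @return Tibble of violations (zero rows when valid).
#' @export
validate_config <- function(config) {
  v <- list()
  if (length(config$strategies) < 1L) {
    v[[1]] <- violation("<config>", "strategies", "at least one strategy required")
  }
  if (anyDuplicated(names(config$strategies))) {
    v[[length(v) + 1L]] <- violation("<config>", "strategies", "duplicate strategy names")
  }
  if (!is.null(config$coefficients) && any(config$coefficients < 0)) {
    v[[length(v) + 1L]] <- violation("<config>", "risk_coefficients",
                                     "coefficients must be >= 0")
  }
  for (strat in config$strategies) {
    built <- tryCatch(build_strategy(strat, config),
                      error = function(e) strat)
    v[[length(v) + 1L]] <- validate_model(built, config$economics)
  }
  dplyr::bind_rows(v)
}
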