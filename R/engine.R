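#' Discount factor for a given year index
#'
#' @param rate Annual discount rate as a fraction (e.g. 0.03).
#' @param t Year index (0 = treatment year, undiscounted).
#' @return `1 / (1 + rate)^t`, vectorized over `t`.
#' @export
#' @examples
#' discount_factor(0.03, 0:3)
discount_factor <- function(rate, t) {
  stopifnot(is.numeric(rate), all(rate >= 0))
  if (any(t < 0)) abort("year index t must be non-negative", class = "radcea_domain_error")
  1 / (1 + rate)^t
}

#' Convert a cumulative probability to a constant annual probability
#'
#' Spreads a cumulative probability over a window of annual cycles under a
#' constant hazard, so that recompounding over the window reproduces the
#' cumulative figure: `1 - (1 - p_annual)^window_years = p_cum`.
#'
#' @param p_cum Cumulative probability over the window, in \[0, 1).
#' @param window_years Window length in years (> 0).
#' @return The equivalent annual probability.
#' @export
#' @examples
#' p <- cumulative_to_annual(0.254, 10)
#' 1 - (1 - p)^10  # recompounds to 0.254
cumulative_to_annual <- function(p_cum, window_years) {
  if (any(window_years <= 0)) {
    abort("window_years must be positive", class = "radcea_domain_error")
  }
  if (any(p_cum < 0) || any(p_cum >= 1)) {
    abort("cumulative probability must lie in [0, 1): p_cum = 1 implies infinite hazard",
          class = "radcea_domain_error")
  }
  1 - (1 - p_cum)^(1 / window_years)
}

# Annualized hazard table for a strategy: one row per transition rule with
# its annual probability and applicability window. pooled_share rules split
# the pooled annual hazard in log-survival space so the joint cumulative
# recompounds exactly.
annual_hazards <- function(strategy, horizon = Inf) {
  n <- length(strategy$transitions)
  from <- to <- character(n)
  annual_p <- ws_v <- we_v <- numeric(n)
  for (i in seq_len(n)) {
    tr <- strategy$transitions[[i]]
    ws <- tr$window_start %||% 0
    we <- tr$window_end %||% Inf
    a <- switch(tr$mode,
      annual_probability = tr$value,
      cumulative_over_window = {
        if (!is.finite(we)) we <- horizon
        cumulative_to_annual(tr$value, we - ws)
      },
      pooled_share = {
        pool <- strategy$pooled_events[[tr$pool]]
        if (is.null(pool)) {
          abort(sprintf("transition %d references unknown pooled event '%s'", i, tr$pool),
                class = "radcea_reference_error")
        }
        ws <- pool$window_start %||% 0
        we <- pool$window_end %||% horizon
        1 - (1 - pool$value)^(tr$value / (we - ws))
      },
      abort(sprintf("unknown transition mode '%s'", tr$mode),
            class = "radcea_validation_error")
    )
    from[i] <- tr$from_state; to[i] <- tr$to_state
    annual_p[i] <- a; ws_v[i] <- ws; we_v[i] <- we
  }
  tibble(rule = seq_len(n), from = from, to = to,
         annual_p = annual_p, window_start = ws_v, window_end = we_v)
}

#' Expand dwell-limited states into tunnel sequences
#'
#' Every state with a bounded `max_dwell` D is replaced by `ceiling(D)`
#' one-year tunnel copies feeding `on_dwell_exit`; when D is fractional the
#' final copy carries weight `D - floor(D)` on utility, annual cost and
#' life-years. Exit rules defined on the base state apply from every copy.
#'
#' @param strategy A validated [strategy_model()].
#' @return An object of class `radcea_expanded` with a `states` tibble
#'   (one row per expanded state) used internally by [run_cohort()].
#' @export
expand_tunnels <- function(strategy) {
  base <- strategy$states
  # guard against cyclic dwell-exit chains (structural error)
  for (s in base) {
    seen <- character(0)
    cur <- s
    while (!is.null(cur) && is.finite(cur$max_dwell)) {
      if (cur$name %in% seen) {
        abort(sprintf("cyclic dwell-exit chain through state '%s'", cur$name),
              class = "radcea_structural_error")
      }
      seen <- c(seen, cur$name)
      nxt <- cur$on_dwell_exit
      cur <- if (is.null(nxt)) NULL else base[[nxt]]
    }
  }
  K_all <- vapply(base, function(s)
    if (is.finite(s$max_dwell)) as.integer(ceiling(s$max_dwell - 1e-9)) else 1L,
    integer(1))
  bounded_all <- vapply(base, function(s) is.finite(s$max_dwell), logical(1))
  frac <- vapply(base, function(s)
    if (is.finite(s$max_dwell)) s$max_dwell - (ceiling(s$max_dwell - 1e-9) - 1) else 1,
    numeric(1))
  K_all <- unname(K_all); bounded_all <- unname(bounded_all); frac <- unname(frac)
  copy <- unlist(lapply(K_all, seq_len), use.names = FALSE)
  base_rep <- rep(names(base), K_all)
  n_copies <- rep(K_all, K_all)
  u_rep <- rep(unname(vapply(base, `[[`, numeric(1), "utility")), K_all)
  c_rep <- rep(unname(vapply(base, `[[`, numeric(1), "annual_cost")), K_all)
  st <- tibble(
    name = ifelse(n_copies == 1L, base_rep, paste0(base_rep, "#", copy)),
    base = base_rep, copy = copy, n_copies = n_copies,
    weight = ifelse(copy == n_copies, rep(frac, K_all), 1),
    utility = u_rep,
    annual_cost = c_rep,
    bounded = rep(bounded_all, K_all)
  )
  st$id <- seq_len(nrow(st))
  st$dead <- st$base == "Dead"
  structure(
    list(states = st, strategy = strategy,
         first_copy = setNames(match(unique(st$base), st$base), unique(st$base))),
    class = "radcea_expanded"
  )
}

# Transition matrix and expected one-time cost vector for one window regime.
# Works base state by base state: exit rules are shared by every tunnel copy,
# residual mass advances the tunnel (or stays, for unbounded states).
build_regime <- function(expanded, hz, t0) {
  st <- expanded$states
  strat <- expanded$strategy
  n <- nrow(st)
  P <- matrix(0, n, n)
  oc <- numeric(n)
  sel <- hz$window_start <= t0 & t0 < hz$window_end
  hf <- hz$from[sel]; ht <- hz$to[sel]; hp <- hz$annual_p[sel]
  entry_cost <- vapply(strat$states, `[[`, numeric(1), "entry_cost")
  for (b in names(strat$states)) {
    rows <- which(st$base == b)
    if (b == "Dead") {
      P[cbind(rows, rows)] <- 1
      next
    }
    r <- which(hf == b)
    a_tot <- sum(hp[r])
    if (a_tot > 1 + 1e-12) {
      abort(sprintf("exit probabilities from state '%s' sum to %.4f (> 1) at cycle %g",
                    b, a_tot, t0),
            class = "radcea_runtime_error")
    }
    entry_charge <- 0
    if (length(r) > 0L) {
      agg <- rowsum(hp[r], group = ht[r])  # total annual prob per destination
      for (d in rownames(agg)) {
        dest <- unname(expanded$first_copy[d])
        if (is.na(dest)) {
          abort(sprintf("transition from '%s' targets unknown state '%s'", b, d),
                class = "radcea_reference_error")
        }
        P[rows, dest] <- P[rows, dest] + agg[d, 1]
      }
      entry_charge <- sum(hp[r] * entry_cost[ht[r]] * (ht[r] != b))
    }
    resid <- 1 - a_tot
    s <- strat$states[[b]]
    if (!is.finite(s$max_dwell)) {
      P[cbind(rows, rows)] <- P[cbind(rows, rows)] + resid
      oc[rows] <- entry_charge
    } else {
      last <- rows[length(rows)]
      if (length(rows) > 1L) {
        adv <- rows[-length(rows)]
        P[cbind(adv, adv + 1L)] <- P[cbind(adv, adv + 1L)] + resid
      }
      dest_base <- s$on_dwell_exit
      dest <- unname(expanded$first_copy[dest_base])
      P[last, dest] <- P[last, dest] + resid
      oc[rows] <- entry_charge
      oc[last] <- oc[last] + resid *
        (s$exit_cost + if (dest_base != b) entry_cost[dest_base] else 0)
    }
  }
  list(P = P, onetime = oc)
}

#' Run the annual-cycle cohort simulation for one strategy
#'
#' The cohort starts fully in the strategy's initial state. Cycle 0 applies
#' the acute phase (procedure cost, expected complication cost and one-time
#' QALY decrement, all undiscounted). Each cycle accrues state utility and
#' annual cost on start-of-cycle occupancy (or the start/end mean under
#' half-cycle correction), discounted at the utility and cost rates with the
#' year index counting from 0; transitions apply at cycle end, with entry
#' costs (and dwell-exit costs) charged on the moving fraction at the arrival
#' year index.
#'
#' @param strategy A validated [strategy_model()] whose transitions are fully
#'   specified (late-complication derivation, if any, already applied; see
#'   [build_strategy()]).
#' @param econ An [economic_settings()].
#' @param cycles Number of annual cycles to run. The default `"auto"` runs
#'   `horizon` cycles plus enough slack for every bounded dwell chain to
#'   drain, so dwell-limited states entered late still accrue their full
#'   residual life expectancy. Pass an integer to force an exact horizon.
#' @return An object of class `radcea_cohort`: a list with `trajectory`
#'   (tibble: cycle, state, occupancy, cost, qaly), per-cycle `cycle_costs` /
#'   `cycle_qalys` streams, and a one-row `totals` tibble
#'   (total_cost, total_qalys, life_years).
#' @export
run_cohort <- function(strategy, econ, cycles = "auto") {
  if (identical(cycles, "auto")) {
    slack <- sum(vapply(strategy$states, function(s)
      if (is.finite(s$max_dwell)) ceiling(s$max_dwell) else 0, numeric(1)))
    cycles <- as.integer(ceiling(econ$horizon) + slack)
  }
  cycles <- as.integer(cycles)
  stopifnot(cycles >= 1L)
  expanded <- expand_tunnels(strategy)
  st <- expanded$states
  n <- nrow(st)
  hz <- annual_hazards(strategy, horizon = econ$horizon)
  breaks <- sort(unique(c(0, hz$window_start, hz$window_end[is.finite(hz$window_end)])))
  breaks <- breaks[breaks < cycles]
  regimes <- lapply(breaks, function(b) build_regime(expanded, hz, b))
  regime_of <- findInterval(seq_len(cycles) - 1L, breaks)

  init <- unname(expanded$first_copy[strategy$initial_state])
  if (is.na(init)) {
    abort(sprintf("initial state '%s' not found", strategy$initial_state),
          class = "radcea_reference_error")
  }
  occ <- numeric(n)
  occ[init] <- 1

  u_w <- st$utility * st$weight
  c_w <- st$annual_cost * st$weight
  l_w <- st$weight * as.numeric(!st$dead)
  df_u <- discount_factor(econ$discount_rate_utility, 0:cycles)
  df_c <- discount_factor(econ$discount_rate_cost, 0:cycles)

  cost_mat <- matrix(0, cycles, n)
  qaly_mat <- matrix(0, cycles, n)
  occ_mat <- matrix(0, cycles, n)
  life_years <- 0

  for (t in seq_len(cycles)) {
    reg <- regimes[[regime_of[t]]]
    occ_end <- drop(occ %*% reg$P)
    cons <- sum(occ_end)
    if (abs(cons - 1) > 1e-9) {
      abort(sprintf("occupancy not conserved at cycle %d (sum = %.12f)", t - 1L, cons),
            class = "radcea_runtime_error")
    }
    basis <- if (econ$half_cycle_correction) (occ + occ_end) / 2 else occ
    occ_mat[t, ] <- occ
    qaly_mat[t, ] <- basis * u_w * df_u[t]
    cost_mat[t, ] <- basis * c_w * df_c[t] + occ * reg$onetime * df_c[t + 1L]
    life_years <- life_years + sum(basis * l_w)
    if (t == 1L) {
      ac <- strategy$acute
      cost_mat[1L, init] <- cost_mat[1L, init] + ac$procedure_cost +
        ac$complication_probability * ac$complication_cost +
        strategy$states[[strategy$initial_state]]$entry_cost
      qaly_mat[1L, init] <- qaly_mat[1L, init] -
        ac$complication_probability * ac$complication_disutility
    }
    occ <- occ_end
  }

  # aggregate expanded copies back to base states for reporting
  base_names <- unique(st$base)
  agg <- function(m) {
    out <- sapply(base_names, function(b) rowSums(m[, st$base == b, drop = FALSE]))
    matrix(out, nrow = cycles, dimnames = list(NULL, base_names))
  }
  occ_b <- agg(occ_mat); cost_b <- agg(cost_mat); qaly_b <- agg(qaly_mat)
  trajectory <- tibble(
    cycle = rep(seq_len(cycles) - 1L, times = length(base_names)),
    state = rep(base_names, each = cycles),
    occupancy = as.vector(occ_b),
    cost = as.vector(cost_b),
    qaly = as.vector(qaly_b)
  )
  totals <- tibble(
    strategy = strategy$name,
    total_cost = sum(cost_mat),
    total_qalys = sum(qaly_mat),
    life_years = life_years
  )
  structure(
    list(strategy = strategy$name, trajectory = trajectory,
         cycle_costs = rowSums(cost_mat), cycle_qalys = rowSums(qaly_mat),
         final_occupancy = setNames(colSums(occ_b[cycles, , drop = FALSE]), base_names),
         totals = totals, cycles = cycles, economics = econ),
    class = "radcea_cohort"
  )
}

#' @export
print.radcea_cohort <- function(x, ...) {
  cat(sprintf("<radcea_cohort> strategy %s, %d annual cycles\n", x$strategy, x$cycles))
  print(x$totals)
  invisible(x)
}
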