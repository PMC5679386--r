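# Independent oracles and small model builders shared across tests.

# Matrix-power summation oracle for models with unbounded states and constant
# annual-probability rules (no windows, no entry/exit costs, zero acute
# phase). Deliberately independent of the engine: builds the one-step
# transition matrix straight from the rules and accumulates rewards from
# explicit matrix powers.
matrix_power_totals <- function(strategy, econ, cycles) {
  nms <- names(strategy$states)
  n <- length(nms)
  P <- matrix(0, n, n, dimnames = list(nms, nms))
  for (tr in strategy$transitions) {
    P[tr$from_state, tr$to_state] <- P[tr$from_state, tr$to_state] + tr$value
  }
  diag(P) <- diag(P) + 1 - rowSums(P)
  u <- vapply(strategy$states, `[[`, numeric(1), "utility")
  cost <- vapply(strategy$states, `[[`, numeric(1), "annual_cost")
  occ <- setNames(numeric(n), nms)
  occ[strategy$initial_state] <- 1
  total_q <- total_c <- 0
  for (t in seq_len(cycles) - 1) {
    total_q <- total_q + sum(occ * u) / (1 + econ$discount_rate_utility)^t
    total_c <- total_c + sum(occ * cost) / (1 + econ$discount_rate_cost)^t
    occ <- drop(occ %*% P)
  }
  list(total_qalys = total_q, total_cost = total_c)
}

# Random constant-probability model in the oracle's domain (2-4 states,
# unbounded, annual rules only).
random_constant_model <- function(seed, n_states) {
  set.seed(seed)
  alive <- paste0("A", seq_len(n_states - 1L))
  states <- c(
    lapply(alive, function(nm) {
      health_state(nm, annual_cost = round(runif(1, 0, 5000), 2),
                   utility = runif(1))
    }),
    list(health_state("Dead", utility = 0))
  )
  transitions <- list()
  for (i in seq_along(alive)) {
    targets <- setdiff(c(alive, "Dead"), alive[i])
    probs <- runif(length(targets))
    probs <- 0.8 * probs / sum(probs)
    for (j in seq_along(targets)) {
      transitions[[length(transitions) + 1L]] <- transition_rule(
        alive[i], targets[j], "annual_probability", value = probs[j])
    }
  }
  strategy_model(name = paste0("cm", seed), states = states,
                 transitions = transitions, initial_state = "A1")
}

# Two-strategy toy config in which the NMB difference is exactly linear in
# one strategy's procedure cost: dNMB(x) = nmb_A(x) - nmb_B has its root at
# x_root = x0 + (nmb_A(x0) - nmb_B), since raising the procedure cost by one
# dollar lowers NMB by one dollar.
linear_threshold_config <- function(p_death = 0.1) {
  strat <- function(nm, proc) {
    strategy_model(
      name = nm,
      acute = acute_phase(procedure_cost = proc),
      states = list(health_state("Alive", annual_cost = 500, utility = 0.8),
                    health_state("Dead", utility = 0)),
      transitions = list(
        transition_rule("Alive", "Dead", "annual_probability", value = p_death)),
      initial_state = "Alive"
    )
  }
  radcea_config(
    economics = economic_settings(horizon = 20),
    strategies = list(strat("A", 1000), strat("B", 4000))
  )
}
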