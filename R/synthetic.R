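# Seeded generators for property tests and closed-form oracle models.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random valid strategy model
#'
#' Deterministic given `seed`; always valid by construction (exit
#' probabilities renormalized below 1, one absorbing `Dead` state, bounded
#' dwells wired to `Dead`). Utilities are uniform on \[0, 1\]; costs are
#' log-uniform.
#'
#' @param seed Integer seed (no global RNG state is consumed).
#' @param n_states Total number of states including `Dead` (>= 2).
#' @return A [strategy_model()].
#' @export
random_model <- function(seed, n_states = 4L) {
  if (n_states < 2L) {
    abort("n_states must be >= 2 (at least one alive state plus Dead)",
          class = "radcea_domain_error")
  }
  with_local_seed(seed, {
    alive <- paste0("S", seq_len(n_states - 1L))
    states <- lapply(alive, function(nm) {
      bounded <- stats::runif(1) < 0.4
      health_state(
        name = nm,
        annual_cost = round(10^stats::runif(1, 0, 4), 2),
        entry_cost = if (stats::runif(1) < 0.5) round(10^stats::runif(1, 0, 4), 2) else 0,
        utility = stats::runif(1),
        max_dwell = if (bounded) round(stats::runif(1, 0.5, 8), 3) else Inf,
        on_dwell_exit = if (bounded) "Dead" else NULL,
        exit_cost = if (bounded && stats::runif(1) < 0.5) round(10^stats::runif(1, 0, 4), 2) else 0
      )
    })
    states <- c(states, list(health_state("Dead", utility = 0)))
    transitions <- list()
    for (i in seq_along(alive)) {
      targets <- unique(c("Dead",
                          sample(setdiff(c(alive, "Dead"), alive[i]),
                                 size = min(2L, n_states - 1L))))
      probs <- stats::runif(length(targets), 0.01, 0.5)
      probs <- probs / max(1, sum(probs) / 0.9)  # exit mass <= 0.9
      for (j in seq_along(targets)) {
        transitions[[length(transitions) + 1L]] <- transition_rule(
          from_state = alive[i], to_state = targets[j],
          mode = "annual_probability", value = probs[j]
        )
      }
    }
    strategy_model(
      name = sprintf("random-%d", seed),
      acute = acute_phase(
        procedure_cost = round(10^stats::runif(1, 2, 4), 2),
        complication_probability = stats::runif(1, 0, 0.5),
        complication_cost = round(10^stats::runif(1, 2, 4), 2),
        complication_disutility = stats::runif(1, 0, 0.2)
      ),
      states = states, transitions = transitions, initial_state = "S1"
    )
  })
}

#' Two-state toy model with a closed-form QALY total
#'
#' Builds the alive/dead model with a constant annual death probability and
#' returns its analytic discounted QALY total
#' `u * sum_{t=0}^{H-1} ((1 - p) / (1 + r))^t`, the geometric-series oracle
#' for [run_cohort()].
#'
#' @param p_death Constant annual death probability in \[0, 1).
#' @param utility Alive-state utility.
#' @param rate Utility discount rate.
#' @param horizon Number of cycles.
#' @return List with `strategy`, `economics` and `expected_qalys`.
#' @export
closed_form_toy <- function(p_death, utility = 1, rate = 0, horizon = 23) {
  stopifnot(p_death >= 0, p_death < 1)
  strategy <- strategy_model(
    name = "toy",
    states = list(
      health_state("Alive", utility = utility),
      health_state("Dead", utility = 0)
    ),
    transitions = list(
      transition_rule("Alive", "Dead", "annual_probability", value = p_death)
    ),
    initial_state = "Alive"
  )
  t <- seq_len(horizon) - 1
  expected <- utility * sum(((1 - p_death) / (1 + rate))^t)
  list(
    strategy = strategy,
    economics = economic_settings(discount_rate_utility = rate,
                                  discount_rate_cost = rate,
                                  horizon = horizon),
    expected_qalys = expected
  )
}
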