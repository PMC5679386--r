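test_that("discount factors follow 1/(1+r)^t", {
  expect_equal(discount_factor(0.03, 0), 1.0)
  expect_equal(discount_factor(0, 10), 1.0)
  expect_equal(discount_factor(0.03, 1), 0.970874, tolerance = 1e-6)
  expect_equal(discount_factor(0.03, 0:5), 1 / 1.03^(0:5))
  expect_true(all(diff(discount_factor(0.05, 0:30)) < 0))
  expect_error(discount_factor(0.03, -1), class = "radcea_domain_error")
})

test_that("cumulative-to-annual conversion recompounds exactly", {
  expect_equal(cumulative_to_annual(0, 10), 0)
  for (p in c(0.254, 0.23, 0.0031, 0.9)) {
    a <- cumulative_to_annual(p, 10)
    expect_equal(1 - (1 - a)^10, p, tolerance = 1e-12)
  }
  expect_error(cumulative_to_annual(1, 10), class = "radcea_domain_error")
  expect_error(cumulative_to_annual(0.5, 0), class = "radcea_domain_error")
})

test_that("tunnel expansion preserves unbounded models and splits dwells", {
  toy <- closed_form_toy(0.1)$strategy
  expect_equal(nrow(expand_tunnels(toy)$states), length(toy$states))

  met6 <- strategy_model(
    name = "m", initial_state = "M",
    states = list(health_state("M", utility = 1, max_dwell = 6,
                               on_dwell_exit = "Dead"),
                  health_state("Dead", utility = 0)),
    transitions = list())
  st <- expand_tunnels(met6)$states
  expect_equal(sum(st$base == "M"), 6L)
  expect_equal(st$weight[st$base == "M"], rep(1, 6))

  met <- strategy_model(
    name = "m", initial_state = "M",
    states = list(health_state("M", utility = 1, max_dwell = 5.625,
                               on_dwell_exit = "Dead"),
                  health_state("Dead", utility = 0)),
    transitions = list())
  st <- expand_tunnels(met)$states
  expect_equal(sum(st$base == "M"), 6L)
  expect_equal(st$weight[st$base == "M"], c(1, 1, 1, 1, 1, 0.625))
  # an entrant's expected dwell equals the fractional limit by summation
  res <- run_cohort(met, economic_settings(discount_rate_utility = 0,
                                           discount_rate_cost = 0, horizon = 10))
  expect_equal(res$totals$total_qalys, 5.625)
  expect_equal(res$totals$life_years, 5.625)
})

test_that("cyclic dwell-exit chains are a structural error", {
  bad <- strategy_model(
    name = "cyc", initial_state = "A",
    states = list(
      health_state("A", utility = 0.5, max_dwell = 2, on_dwell_exit = "B"),
      health_state("B", utility = 0.5, max_dwell = 2, on_dwell_exit = "A"),
      health_state("Dead", utility = 0)),
    transitions = list())
  expect_error(expand_tunnels(bad), class = "radcea_structural_error")
})

test_that("a deathless cohort accrues exactly horizon QALYs", {
  toy <- closed_form_toy(0, utility = 1, rate = 0, horizon = 23)
  res <- run_cohort(toy$strategy, toy$economics)
  expect_identical(res$cycles, 23L)
  expect_equal(res$totals$total_qalys, 23)
  expect_equal(res$totals$life_years, 23)
})

test_that("engine matches the geometric closed form on 50 toy parameterizations", {
  set.seed(101)
  for (i in 1:50) {
    p <- runif(1, 0, 0.6)
    u <- runif(1)
    r <- runif(1, 0, 0.08)
    H <- sample(5:40, 1)
    toy <- closed_form_toy(p, u, r, H)
    res <- run_cohort(toy$strategy, toy$economics)
    expect_equal(res$totals$total_qalys, toy$expected_qalys, tolerance = 1e-10)
  }
})

test_that("engine totals equal the matrix-power oracle on 2-4 state models", {
  for (seed in 1:20) {
    n <- 2L + (seed %% 3L)
    strat <- random_constant_model(seed, n)
    econ <- economic_settings(discount_rate_cost = 0.03,
                              discount_rate_utility = 0.015, horizon = 17)
    res <- run_cohort(strat, econ, cycles = 17)
    oracle <- matrix_power_totals(strat, econ, 17)
    expect_equal(res$totals$total_qalys, oracle$total_qalys, tolerance = 1e-10)
    expect_equal(res$totals$total_cost, oracle$total_cost, tolerance = 1e-10)
  }
})

test_that("occupancy is conserved every cycle on 100 seeded random models", {
  econ <- economic_settings(horizon = 15)
  for (seed in 1:100) {
    strat <- random_model(seed, n_states = 2L + (seed %% 4L))
    res <- run_cohort(strat, econ)
    sums <- tapply(res$trajectory$occupancy, res$trajectory$cycle, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(res$trajectory$occupancy >= -1e-15 &
                      res$trajectory$occupancy <= 1 + 1e-15))
  }
})

test_that("discounting never increases totals, with equality at rate zero", {
  strat <- random_model(7, 4)
  run_at <- function(ru, rc) {
    run_cohort(strat, economic_settings(discount_rate_utility = ru,
                                        discount_rate_cost = rc,
                                        horizon = 20), cycles = 20)$totals
  }
  t0 <- run_at(0, 0)
  t3 <- run_at(0.03, 0.03)
  expect_lt(t3$total_qalys, t0$total_qalys)
  expect_lt(t3$total_cost, t0$total_cost)
  expect_equal(run_at(0, 0)$total_qalys, t0$total_qalys)
})

test_that("raising a utility or a cost never lowers the corresponding total", {
  econ <- economic_settings(horizon = 15)
  for (seed in c(3, 11, 19)) {
    strat <- random_model(seed, 4)
    base <- run_cohort(strat, econ)$totals
    up <- strat
    up$states$S1$utility <- min(1, up$states$S1$utility + 0.2)
    expect_gte(run_cohort(up, econ)$totals$total_qalys, base$total_qalys)
    up2 <- strat
    up2$states$S1$annual_cost <- up2$states$S1$annual_cost + 500
    expect_gte(run_cohort(up2, econ)$totals$total_cost, base$total_cost)
  }
})

test_that("cycle streams are prefix-stable under a longer horizon", {
  strat <- iort_ebrt_fixture()$strategies$IORT
  econ <- iort_ebrt_fixture()$economics
  short <- run_cohort(strat, econ, cycles = 12)
  long <- run_cohort(strat, econ, cycles = 30)
  expect_equal(short$cycle_qalys, long$cycle_qalys[1:12], tolerance = 1e-12)
  expect_equal(short$cycle_costs, long$cycle_costs[1:12], tolerance = 1e-12)
  expect_equal(long$totals$total_qalys,
               sum(short$cycle_qalys) + sum(long$cycle_qalys[13:30]),
               tolerance = 1e-12)
})

test_that("runtime probability-mass violations name the state", {
  bad <- strategy_model(
    name = "bad", initial_state = "A",
    states = list(health_state("A", utility = 1),
                  health_state("Dead", utility = 0)),
    transitions = list(
      transition_rule("A", "Dead", "annual_probability", value = 0.8),
      transition_rule("A", "Dead", "annual_probability", value = 0.6)))
  expect_error(run_cohort(bad, economic_settings(horizon = 5)),
               "from state 'A'", class = "radcea_runtime_error")
})

test_that("the acute phase charges expected one-time cost and disutility at cycle 0", {
  toy <- closed_form_toy(0, utility = 1, rate = 0, horizon = 5)
  strat <- toy$strategy
  strat$acute <- acute_phase(procedure_cost = 1000,
                             complication_probability = 0.3,
                             complication_cost = 2000,
                             complication_disutility = 0.4)
  res <- run_cohort(strat, toy$economics)
  expect_equal(res$cycle_costs[1], 1000 + 0.3 * 2000)
  expect_equal(res$totals$total_qalys, 5 - 0.3 * 0.4)
})

test_that("entry and dwell-exit costs are charged on the moving fraction", {
  # A (unbounded) -> B (entry 100, dwell 1, exit 50) -> Dead, p = 0.5, r = 0
  strat <- strategy_model(
    name = "flow", initial_state = "A",
    states = list(
      health_state("A", utility = 1),
      health_state("B", utility = 1, entry_cost = 100, exit_cost = 50,
                   max_dwell = 1, on_dwell_exit = "Dead"),
      health_state("Dead", utility = 0)),
    transitions = list(
      transition_rule("A", "B", "annual_probability", value = 0.5)))
  econ <- economic_settings(discount_rate_cost = 0, discount_rate_utility = 0,
                            horizon = 3)
  res <- run_cohort(strat, econ, cycles = 3)
  # entries to B: 0.5 after cycle 0, 0.25 after cycle 1, 0.125 after cycle 2;
  # each entrant pays 100 on entry and 50 one cycle later at dwell exit
  expect_equal(sum(res$cycle_costs),
               (0.5 + 0.25 + 0.125) * 100 + (0.5 + 0.25) * 50)
})

test_that("half-cycle correction averages start and end occupancy", {
  toy <- closed_form_toy(0.2, utility = 1, rate = 0, horizon = 4)
  econ_hc <- toy$economics
  econ_hc$half_cycle_correction <- TRUE
  res <- run_cohort(toy$strategy, econ_hc)
  alive <- 0.8^(0:4)
  expect_equal(res$totals$total_qalys, sum((alive[1:4] + alive[2:5]) / 2))
})

test_that("a windowed transition only applies inside its window", {
  strat <- strategy_model(
    name = "win", initial_state = "A",
    states = list(health_state("A", utility = 1),
                  health_state("Dead", utility = 0)),
    transitions = list(
      transition_rule("A", "Dead", "cumulative_over_window", value = 0.5,
                      window_start = 2, window_end = 4)))
  res <- run_cohort(strat, economic_settings(discount_rate_utility = 0,
                                             horizon = 6), cycles = 6)
  a <- cumulative_to_annual(0.5, 2)
  expect_equal(res$cycle_qalys, c(1, 1, 1, 1 - a, (1 - a)^2, (1 - a)^2))
})
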