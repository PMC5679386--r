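test_that("a degenerate sweep returns nearly identical NMB pairs", {
  cfg <- linear_threshold_config()
  sw <- one_way_sweep(cfg, param_path = "strategies.A.acute.procedure_cost",
                      low = 1000, high = 1000.001, n_points = 2)
  expect_equal(nrow(sw), 4L)
  by_strat <- split(sw$nmb, sw$strategy)
  expect_equal(by_strat$A[1], by_strat$A[2], tolerance = 1e-6)
  expect_equal(by_strat$B[1], by_strat$B[2], tolerance = 1e-12)
})

test_that("sweeping a parameter the model never reads leaves NMB constant", {
  cfg <- iort_ebrt_fixture()
  # detach local/regional recurrence: its annual cost is then never accrued
  cfg <- config_set(cfg, "strategies.*.transitions.1.value", 0)
  sw <- one_way_sweep(cfg,
                      param_path = "strategies.*.states.LocalRegional.annual_cost",
                      low = 0, high = 50000, n_points = 5)
  for (s in unique(sw$strategy)) {
    expect_equal(diff(range(sw$nmb[sw$strategy == s])), 0, tolerance = 1e-8)
  }
})

test_that("lowering the well utility erodes the IORT advantage monotonically", {
  sw <- one_way_sweep(iort_ebrt_fixture(),
                      param_path = "strategies.*.states.Well.utility",
                      low = 0, high = 0.92, n_points = 7)
  iort <- sw$nmb[sw$strategy == "IORT"]
  margin <- iort - sw$nmb[sw$strategy == "EBRT"]
  expect_true(all(diff(iort) > 0))    # NMB rises with utility
  expect_true(all(diff(margin) > 0))  # advantage shrinks toward low utility
  expect_true(all(margin > 0))        # IORT preferred across the whole range
})

test_that("an invalid perturbed point is reported with its parameter value", {
  expect_error(
    one_way_sweep(iort_ebrt_fixture(),
                  param_path = "strategies.*.states.Well.utility",
                  low = 0.9, high = 1.5, n_points = 3),
    "utility", class = "radcea_validation_error")
})

test_that("tornado entries are ordered by independently recomputed spreads", {
  cfg <- iort_ebrt_fixture()
  ranges <- fixture_sensitivity_ranges()[c("well_utility",
                                           "iort_event_probability",
                                           "ebrt_event_probability")]
  tor <- tornado(cfg, ranges)
  expect_equal(nrow(tor), 3L)
  expect_equal(attr(tor, "strategy"), "IORT")
  expect_true(all(diff(tor$spread) <= 0))
  expect_equal(tor$spread, abs(tor$nmb_at_high - tor$nmb_at_low))
  # re-sort oracle: recompute each spread from scratch with one_way_sweep
  recomputed <- vapply(ranges, function(r) {
    sw <- one_way_sweep(cfg, sensitivity_range(r$param_path, r$low, r$high, 2))
    vals <- sw$nmb[sw$strategy == "IORT"]
    abs(vals[2] - vals[1])
  }, numeric(1))
  expect_equal(sort(tor$spread, decreasing = TRUE),
               unname(sort(recomputed, decreasing = TRUE)), tolerance = 1e-9)

  single <- tornado(cfg, ranges["well_utility"])
  expect_equal(nrow(single), 1L)
})

test_that("tornado spread is invariant to evaluating the range in either order", {
  cfg <- linear_threshold_config()
  r <- sensitivity_range("strategies.A.acute.procedure_cost", 500, 3000, 2)
  tor <- tornado(cfg, list(r))
  sw <- one_way_sweep(cfg, r)
  a <- sw$nmb[sw$strategy == "A"]
  expect_equal(tor$spread, abs(a[1] - a[2]))
  expect_equal(tor$spread, abs(rev(a)[1] - rev(a)[2]))
})

test_that("bisection finds the closed-form root of a linear NMB difference", {
  cfg <- linear_threshold_config()
  base <- radcea:::config_nmb(cfg)
  x_root <- 1000 + unname(base["A"] - base["B"])  # dNMB falls $1 per $1 of cost
  expect_equal(x_root, 4000)  # arms identical except procedure cost
  thr <- find_threshold(cfg, "strategies.A.acute.procedure_cost",
                        bounds = c(1000, 8000))
  expect_equal(thr$threshold, x_root, tolerance = 2 * thr$tolerance + 1e-9)
  expect_equal(thr$preferred_below, "A")
  expect_equal(thr$preferred_above, "B")
})

test_that("bisection agrees with a dense 10,000-point scan of the analytic difference", {
  cfg <- linear_threshold_config()
  base <- radcea:::config_nmb(cfg)
  delta_analytic <- function(x) unname(base["A"] - base["B"]) - (x - 1000)
  xs <- seq(1000, 8000, length.out = 10000)
  ds <- delta_analytic(xs)
  i <- which(ds[-10000] * ds[-1] < 0)
  grid_root <- (xs[i] + xs[i + 1]) / 2
  spacing <- xs[2] - xs[1]
  thr <- find_threshold(cfg, "strategies.A.acute.procedure_cost",
                        bounds = c(1000, 8000))
  expect_lt(abs(thr$threshold - grid_root), spacing)
})

test_that("the NMB difference changes sign across the reported threshold", {
  cfg <- linear_threshold_config()
  thr <- find_threshold(cfg, "strategies.A.acute.procedure_cost",
                        bounds = c(1000, 8000), tolerance = 0.01)
  d_at <- function(x) {
    v <- radcea:::config_nmb(config_set(cfg, "strategies.A.acute.procedure_cost", x))
    unname(v["A"] - v["B"])
  }
  expect_gt(d_at(thr$threshold - 0.02), 0)
  expect_lt(d_at(thr$threshold + 0.02), 0)
})

test_that("a parameter with no effect reports none-in-range", {
  cfg <- linear_threshold_config()
  # B's alive-state annual cost affects only B; sweep a state nobody enters:
  # detach the transition by sweeping a no-op scalar instead
  cfg2 <- config_set(cfg, "strategies.A.acute.complication_probability", 0)
  thr <- find_threshold(cfg2, "strategies.A.acute.complication_cost",
                        bounds = c(0, 1e6))
  expect_true(is.na(thr$threshold))
  expect_equal(thr$preferred_below, thr$preferred_above)
})
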