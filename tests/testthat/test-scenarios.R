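full <- rounding_policy("full_precision")

# one-year staple: 3.65 MT supply at 10 g/day makes the daily-use estimate
# divide out exactly (1,000 people at 365 use days)
staple <- function() {
  fm_config(sales_mt = 3.65, base_daily = 10, use_days = 365,
            start = "2021-01", end = "2021-12")
}

test_that("use-frequency scenarios scale reach inversely with use days", {
  sc <- list(
    scenario_spec("daily_use_all_year", list("use.use_days" = 365)),
    scenario_spec("single_trial_day", list("use.use_days" = 1))
  )
  rng <- run_scenarios(staple(), sc, full)
  expect_identical(rng$low_scenario, "daily_use_all_year")  # conservative bound
  expect_identical(rng$high_scenario, "single_trial_day")
  expect_identical(rng$low_reach, 1000)
  expect_identical(rng$high_reach, 365 * rng$low_reach)
})

test_that("identical scenarios collapse the range to a point", {
  sc <- list(scenario_spec("a", list("supply.quality_factor" = 0.9)),
             scenario_spec("b", list("supply.quality_factor" = 0.9)))
  rng <- run_scenarios(staple(), sc, full)
  expect_identical(rng$low_reach, rng$high_reach)
})

test_that("halving the quality factor halves reach within rounding", {
  sc <- list(scenario_spec("base", list("supply.quality_factor" = 1)),
             scenario_spec("half_quality", list("supply.quality_factor" = 0.5)))
  rng <- run_scenarios(brazil_config(), sc, full)
  expect_lte(abs(rng$high_reach - 2 * rng$low_reach), 2)
  expect_identical(rng$high_scenario, "base")
})

test_that("scenario bounds bracket the base estimate when it is included", {
  base <- staple()
  sc <- list(scenario_spec("base", list("use.use_days" = 365)),
             scenario_spec("low_use", list("use.use_days" = 36.5)),
             scenario_spec("high_quality", list("supply.quality_factor" = 1)))
  rng <- run_scenarios(base, sc, full)
  base_reach <- estimate_reach(validate_config(base), full)$total_reach
  expect_lte(rng$low_reach, base_reach)
  expect_gte(rng$high_reach, base_reach)
})

test_that("unknown override paths are rejected by name", {
  sc <- list(scenario_spec("a", list("use.no_such_field" = 1)),
             scenario_spec("b", list("use.use_days" = 10)))
  expect_error(run_scenarios(staple(), sc, full),
               "use.no_such_field", class = "reach_validation_error")
})

test_that("overridden values pass the base field's validation", {
  sc <- list(scenario_spec("bad", list("supply.quality_factor" = 1.5)),
             scenario_spec("ok", list("supply.quality_factor" = 1)))
  expect_error(run_scenarios(staple(), sc, full),
               class = "reach_validation_error")
})

test_that("sensitivity sweeps scale linearly in supply-side factors", {
  tab <- sensitivity_sweep(staple(), "supply.quality_factor",
                           c(1.0, 0.9, 0.8), full)
  expect_identical(tab$value, c(1.0, 0.9, 0.8))
  expect_identical(tab$total_reach, c(1000, 900, 800))

  one <- sensitivity_sweep(staple(), "supply.losses_factor", 0.5, full)
  expect_identical(nrow(one), 1L)
  expect_identical(one$total_reach, 500)
})

test_that("sweeping use days shows inverse proportionality", {
  cfg <- fm_config(sales_mt = 100, base_daily = 32.7, use_days = 819,
                   start = "2013-02", end = "2015-04")
  tab <- sensitivity_sweep(cfg, "use.use_days", c(819, 409.5), full)
  expect_lte(abs(tab$total_reach[2] - 2 * tab$total_reach[1]), 1)
})

test_that("reach is monotone along sweeps of use and supply parameters", {
  cfg <- staple()
  use_tab <- sensitivity_sweep(cfg, "use.use_days", c(30, 90, 180, 365), full)
  expect_true(all(diff(use_tab$total_reach) <= 0))
  amt_tab <- sensitivity_sweep(cfg, "use.base_daily_amount",
                               c(5, 10, 20, 40), full)
  expect_true(all(diff(amt_tab$total_reach) <= 0))
  q_tab <- sensitivity_sweep(cfg, "supply.quality_factor",
                             c(0.25, 0.5, 0.75, 1), full)
  expect_true(all(diff(q_tab$total_reach) >= 0))
  s_tab <- sensitivity_sweep(cfg, "supply.sales_volume",
                             c(1, 2, 3.65, 10), full)
  expect_true(all(diff(s_tab$total_reach) >= 0))
})

test_that("run_scenarios requires at least two scenario specs", {
  expect_error(run_scenarios(staple(),
                             list(scenario_spec("only", list("use.use_days" = 1))),
                             full),
               class = "reach_validation_error")
})
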