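test_that("period day counts follow the whole-calendar-month convention", {
  cases <- list(
    list(start = "2013-02", end = "2015-04", days = 819L),  # 27-month window
    list(start = "2021-01", end = "2021-01", days = 31L),
    list(start = "2016-02", end = "2016-02", days = 29L),   # leap February
    list(start = "2015-02", end = "2015-02", days = 28L),
    list(start = "2020-01", end = "2020-12", days = 366L)   # leap year
  )
  for (cs in cases) {
    expect_identical(period_length_days(reach_period(cs$start, cs$end)),
                     cs$days)
  }
  expect_identical(period_length_months(reach_period("2013-02", "2015-04")), 27L)
  expect_error(reach_period("2015-04", "2013-02"),
               class = "reach_validation_error")
})

test_that("the one-month convention is 30.4 days and is not the period average", {
  expect_identical(average_month_days(), 30.4)
  expect_equal(12 * average_month_days(), 364.8)
  # a 27-month/819-day window averages 30.33 days/month; the quoted
  # one-month duration convention deliberately stays at 30.4
  expect_false(isTRUE(all.equal(average_month_days(), 819 / 27)))
})

test_that("total supply handles both measurement modes, units, and leakage", {
  sales <- supply_inputs("sales_distribution", sales_volume = 11174.56,
                         unit = "metric_tons")
  expect_identical(total_supply(sales), 11174560000)

  flows0 <- supply_inputs("production_flows", production = 100, exports = 100,
                          unit = "grams")
  expect_identical(total_supply(flows0), 0)

  flows <- supply_inputs("production_flows", production = 500, exports = 200,
                         imports = 100, leakage_fraction = 0.1, unit = "grams")
  expect_equal(total_supply(flows), 360)

  kg <- supply_inputs("sales_distribution", sales_volume = 2, unit = "kilograms")
  expect_identical(total_supply(kg), 2000)

  expect_error(
    total_supply(supply_inputs("production_flows", production = 10,
                               exports = 50, unit = "grams")),
    class = "reach_arithmetic_error"
  )
})

test_that("flows mode equals sales mode when sales = production - exports + imports", {
  set.seed(42)
  for (i in 1:50) {
    prod_ <- runif(1, 0, 1000)
    exp_ <- runif(1, 0, prod_)
    imp_ <- runif(1, 0, 500)
    leak <- runif(1, 0, 0.5)
    s <- total_supply(supply_inputs("sales_distribution",
                                    sales_volume = prod_ - exp_ + imp_,
                                    leakage_fraction = leak, unit = "grams"))
    f <- total_supply(supply_inputs("production_flows", production = prod_,
                                    exports = exp_, imports = imp_,
                                    leakage_fraction = leak, unit = "grams"))
    expect_equal(s, f)
  }
})

test_that("effective supply multiplies through the adjustment factors", {
  expect_identical(effective_supply(11174560000, adjustment_factors(1, 1))$quantity,
                   11174560000)
  expect_identical(effective_supply(5000, adjustment_factors(0, 1))$quantity, 0)
  expect_equal(effective_supply(1000, adjustment_factors(0.9, 0.8))$quantity, 720)
})

test_that("effective supply is monotone in total and factors, identity at (1,1)", {
  set.seed(7)
  for (i in 1:50) {
    t1 <- runif(1, 0, 1e6); t2 <- t1 + runif(1, 0, 1e5)
    q1 <- runif(1); q2 <- min(1, q1 + runif(1, 0, 0.3))
    l1 <- runif(1); l2 <- min(1, l1 + runif(1, 0, 0.3))
    expect_lte(effective_supply(t1, adjustment_factors(q1, l1))$quantity,
               effective_supply(t2, adjustment_factors(q1, l1))$quantity)
    expect_lte(effective_supply(t1, adjustment_factors(q1, l1))$quantity,
               effective_supply(t1, adjustment_factors(q2, l1))$quantity)
    expect_lte(effective_supply(t1, adjustment_factors(q1, l1))$quantity,
               effective_supply(t1, adjustment_factors(q1, l2))$quantity)
    expect_identical(effective_supply(t1, adjustment_factors(1, 1))$quantity, t1)
    # adjusted quantity never exceeds the unadjusted total
    expect_lte(effective_supply(t1, adjustment_factors(q1, l1))$quantity, t1)
  }
})

test_that("supply input validation rejects out-of-range or mismatched fields", {
  expect_error(supply_inputs("sales_distribution", unit = "grams"),
               class = "reach_validation_error")
  expect_error(supply_inputs("sales_distribution", sales_volume = -1,
                             unit = "grams"),
               class = "reach_validation_error")
  expect_error(supply_inputs("sales_distribution", sales_volume = 10,
                             leakage_fraction = 1.5, unit = "grams"),
               class = "reach_validation_error")
  expect_error(supply_inputs("production_flows", sales_volume = 10,
                             production = 5, unit = "grams"),
               class = "reach_validation_error")
  expect_error(adjustment_factors(quality_factor = 1.2),
               class = "reach_validation_error")
})

test_that("half-up rounding rounds 0.5 away from zero at any precision", {
  expect_identical(round_half_up(0.5), 1)
  expect_identical(round_half_up(1.5), 2)   # banker's rounding would give 2 anyway
  expect_identical(round_half_up(2.5), 3)   # ...but not here
  expect_identical(round_half_up(4036.8), 4037)
  expect_identical(round_half_up(32.7012, 1), 32.7)
  expect_identical(round_half_up(9163.1392, 2), 9163.14)
  expect_identical(round_half_up(-2.5), -3)
})
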