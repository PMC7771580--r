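repl <- rounding_policy("replication")
full <- rounding_policy("full_precision")

test_that("effective daily amount chains base, multipliers, and divisor", {
  rice <- fast_moving_use(160.3, use_days = "period",
                          multipliers = c(at_home = 0.85, product_share = 0.60),
                          conversion_divisor = 2.5)
  expect_identical(effective_daily_amount(rice, repl), 32.7)
  expect_equal(effective_daily_amount(rice, full), 160.3 * 0.85 * 0.6 / 2.5)

  plain <- fast_moving_use(40, use_days = 100)
  expect_identical(effective_daily_amount(plain, repl), 40)

  halved <- fast_moving_use(100, use_days = 10,
                            multipliers = c(a = 0.5, b = 0.5),
                            conversion_divisor = 2)
  expect_equal(effective_daily_amount(halved, full), 12.5)
})

test_that("effective daily amount is invariant to multiplier order", {
  set.seed(11)
  for (i in 1:25) {
    m <- runif(sample(2:4, 1))
    names(m) <- paste0("m", seq_along(m))
    base <- runif(1, 1, 200)
    a <- fast_moving_use(base, use_days = 1, multipliers = m)
    b <- fast_moving_use(base, use_days = 1, multipliers = rev(m))
    expect_equal(effective_daily_amount(a, full), effective_daily_amount(b, full))
  }
})

test_that("per-consumer period use multiplies daily amount by use days", {
  expect_identical(per_consumer_period_use(32.7, 819, repl)$quantity, 26781)
  expect_identical(per_consumer_period_use(32.7, 30.4, repl)$quantity, 994)
  expect_identical(per_consumer_period_use(1, 1, repl)$quantity, 1)
  expect_error(per_consumer_period_use(32.7, 900, repl, period_days = 819),
               class = "reach_validation_error")
})

test_that("per-consumer use is linear in use_days under full precision", {
  set.seed(12)
  for (i in 1:25) {
    d <- runif(1, 1, 100); days <- runif(1, 1, 400); k <- sample(2:5, 1)
    expect_equal(per_consumer_period_use(d, k * days, full)$quantity,
                 k * per_consumer_period_use(d, days, full)$quantity)
  }
})

test_that("users per unit handles scalars and household distributions", {
  cup <- durable_use(users_per_unit = 1, length_of_use_days = 365)
  expect_identical(users_per_unit(cup), 1)

  latrines <- durable_use(
    household_distribution = list(list(weight = 0.3, users = 4),
                                  list(weight = 0.5, users = 6),
                                  list(weight = 0.2, users = 9)),
    length_of_use_days = 3650)
  expect_equal(users_per_unit(latrines), 6.0)

  degenerate <- durable_use(household_distribution = list(
    list(weight = 1.0, users = 5)), length_of_use_days = 100)
  expect_identical(users_per_unit(degenerate), 5)

  expect_error(
    durable_use(household_distribution = list(list(weight = 0.5, users = 4),
                                              list(weight = 0.4, users = 6)),
                length_of_use_days = 100),
    class = "reach_validation_error")
  expect_error(durable_use(users_per_unit = 2,
                           household_distribution = list(
                             list(weight = 1, users = 2)),
                           length_of_use_days = 10),
               class = "reach_validation_error")
})

test_that("distribution-averaged users lie within the component range", {
  set.seed(13)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    w <- runif(k); w <- w / sum(w)
    u <- sample(1:12, k, replace = TRUE)
    spec <- durable_use(
      household_distribution = lapply(seq_len(k), function(j)
        list(weight = w[j], users = u[j])),
      length_of_use_days = 100)
    d <- users_per_unit(spec)
    expect_gte(d, min(u))
    expect_lte(d, max(u))
  }
})

test_that("turnover is period/length-of-use, floored at one unit per consumer", {
  expect_identical(turnover_units(5 * 365, 365), 5)
  expect_identical(turnover_units(365, 3650), 1)
  expect_equal(turnover_units(900, 600), 1.5)
  expect_identical(turnover_units(400, 400), 1)  # boundary: exactly one unit
  set.seed(14)
  for (i in 1:50) {
    expect_gte(turnover_units(runif(1, 1, 2000), runif(1, 1, 2000)), 1)
  }
})
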