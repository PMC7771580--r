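repl <- rounding_policy("replication")
full <- rounding_policy("full_precision")

test_that("coverage x population gives reach (F1), and back again", {
  expect_identical(reach_from_coverage(coverage_input(0.5, 1e6))$total_reach,
                   5e5)
  expect_identical(reach_from_coverage(coverage_input(0, 12345))$total_reach, 0)
  expect_identical(
    reach_from_coverage(coverage_input(0.327, 12345))$total_reach, 4037)

  expect_identical(as.numeric(coverage_from_reach(500000, 1e6)), 0.5)
  expect_identical(as.numeric(coverage_from_reach(0, 100)), 0)
  expect_equal(as.numeric(coverage_from_reach(2365712, 202768562)),
               2365712 / 202768562)
  expect_true(attr(coverage_from_reach(150, 100), "exceeds_population"))
  expect_false(attr(coverage_from_reach(50, 100), "exceeds_population"))
  expect_error(coverage_from_reach(10, 0), class = "reach_arithmetic_error")
})

test_that("coverage -> reach -> coverage is the identity within one person", {
  set.seed(21)
  for (i in 1:50) {
    pop <- sample(1000:1e7, 1)
    cov <- runif(1)
    reach <- reach_from_coverage(coverage_input(cov, pop))$total_reach
    cov2 <- as.numeric(coverage_from_reach(reach, pop))
    expect_lte(abs(cov2 * pop - cov * pop), 1)
  }
})

test_that("fast-moving reach divides effective supply by per-consumer use", {
  s <- effective_supply(11174.56e6)
  u <- per_consumer_period_use(32.7, 819, repl)
  expect_identical(reach_fast_moving(s, u, repl)$total_reach, 417257)

  expect_identical(
    reach_fast_moving(effective_supply(0),
                      per_consumer_period_use(10, 10, full), full)$total_reach,
    0)
  expect_identical(
    reach_fast_moving(effective_supply(1000),
                      per_consumer_period_use(25, 10, full), full)$total_reach,
    4)
})

test_that("fast-moving reach conserves supply and is monotone", {
  set.seed(22)
  for (i in 1:50) {
    supply <- runif(1, 1e3, 1e10)
    use_g <- runif(1, 10, 1e5)
    res <- reach_fast_moving(effective_supply(supply),
                             per_consumer_period_use(use_g, 1, full), full)
    expect_equal(res$total_reach_exact * use_g, supply)
    # weakly decreasing in per-consumer use, increasing in supply
    res_more_use <- reach_fast_moving(
      effective_supply(supply), per_consumer_period_use(use_g * 2, 1, full), full)
    res_more_supply <- reach_fast_moving(
      effective_supply(supply * 2), per_consumer_period_use(use_g, 1, full), full)
    expect_lte(res_more_use$total_reach, res$total_reach)
    expect_gte(res_more_supply$total_reach, res$total_reach)
  }
})

test_that("durable reach is units x users-per-unit / turnover (F2)", {
  cups <- effective_supply(1000, unit_kind = "units")
  expect_identical(reach_durable(cups, 1, 5)$total_reach, 200)
  latrines <- effective_supply(100, unit_kind = "units")
  expect_identical(reach_durable(latrines, 5, 1)$total_reach, 500)
  none <- effective_supply(0, unit_kind = "units")
  expect_identical(reach_durable(none, 3, 2)$total_reach, 0)
  expect_error(reach_durable(cups, 1, 0.5), class = "reach_validation_error")
})

test_that("segmented reach reproduces the repeat/trial worked example", {
  supply <- effective_supply(11174.56e6)
  daily <- 32.7
  segs <- list(
    consumer_segment("repeat", 0.82, per_consumer_period_use(daily, 819, repl)),
    consumer_segment("trial", 0.18, per_consumer_period_use(daily, 30.4, repl))
  )
  res <- segmented_reach(supply, segs, repl)
  expect_identical(unname(res$segment_reach["repeat"]), 342151)
  expect_identical(unname(res$segment_reach["trial"]), 2023561)
  expect_identical(res$total_reach, 2365712)
  expect_equal(unname(res$details$segment_supply_g),
               c(9163.14e6, 2011.42e6))
})

test_that("a single segment of share 1 reduces to the unsegmented estimate", {
  supply <- effective_supply(5e8)
  use <- per_consumer_period_use(30, 200, full)
  one <- segmented_reach(supply, list(consumer_segment("all", 1, use)), full)
  expect_identical(one$total_reach,
                   reach_fast_moving(supply, use, full)$total_reach)
})

test_that("equal segments with equal use split the single-segment reach", {
  set.seed(23)
  for (i in 1:20) {
    supply <- effective_supply(runif(1, 1e6, 1e9))
    use <- per_consumer_period_use(runif(1, 5, 100), sample(30:400, 1), full)
    single <- reach_fast_moving(supply, use, full)$total_reach
    segs <- list(consumer_segment("a", 0.5, use),
                 consumer_segment("b", 0.5, use))
    split2 <- segmented_reach(supply, segs, full)
    expect_lte(abs(split2$total_reach - single), 2)
    expect_lte(abs(split2$segment_reach[["a"]] - single / 2), 1)
  }
})

test_that("segment shares must sum to one", {
  supply <- effective_supply(1e6)
  use <- per_consumer_period_use(10, 10, full)
  expect_error(
    segmented_reach(supply, list(consumer_segment("a", 0.5, use),
                                 consumer_segment("b", 0.4, use)), full),
    class = "reach_validation_error")
})

test_that("subgroup allocation multiplies total reach by population fractions", {
  subs <- list(subgroup_spec("women_15_49", 0.2814),
               subgroup_spec("children_6m_5y", 0.0654),
               subgroup_spec("lower_ses", 0.741))
  got <- subgroup_reach(2365712, subs, repl)
  expect_identical(unname(got),
                   c(665711, 154718, 1752993))
  expect_identical(unname(subgroup_reach(1234, list(subgroup_spec("all", 1)))),
                   1234)
  # overlapping subgroups are allowed: fractions sum to more than 1 here
  expect_identical(sum(0.2814, 0.0654, 0.741) > 1, TRUE)
  expect_true(all(got <= 2365712))
})

test_that("razor-and-blade combines components by the conservative minimum", {
  razor <- reach_durable(effective_supply(10000, unit_kind = "units"), 1, 1)
  blade <- reach_fast_moving(effective_supply(8000 * 250),
                             per_consumer_period_use(250, 1, full), full)
  expect_identical(razor$total_reach, 10000)
  expect_identical(blade$total_reach, 8000)

  only_razor <- razor_blade_reach(razor = razor)
  expect_identical(only_razor$total_reach, 10000)
  expect_identical(only_razor$formula_used, "F2")

  both <- razor_blade_reach(razor = razor, blade = blade)
  expect_identical(both$total_reach, 8000)
  expect_identical(unname(both$segment_reach),
                   c(10000, 8000))
  expect_identical(both$formula_used, "F3")  # blade is the binding component

  same <- razor_blade_reach(razor = razor, blade = razor)
  expect_identical(same$total_reach, 10000)

  expect_error(razor_blade_reach(), class = "reach_validation_error")
})

test_that("segmented totals match an independent per-segment computation", {
  # brute-force oracle over random small configurations
  set.seed(24)
  for (i in 1:500) {
    supply_g <- runif(1, 1e4, 1e9)
    k <- sample(2:4, 1)
    shares <- runif(k); shares <- shares / sum(shares)
    uses <- runif(k, 10, 5e4)
    segs <- lapply(seq_len(k), function(j)
      consumer_segment(paste0("s", j), shares[j],
                       per_consumer_period_use(uses[j], 1, full)))
    res <- segmented_reach(effective_supply(supply_g), segs, full)
    oracle <- sum(vapply(seq_len(k), function(j)
      floor(shares[j] * supply_g / uses[j] + 0.5), numeric(1)))
    expect_identical(res$total_reach, oracle)
  }
})
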