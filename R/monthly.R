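#' Month-by-month reach series
#'
#' Computes a reach estimate for each month of the configuration's period
#' from a per-month supply breakdown (e.g. from [load_supply_ledger()]),
#' useful for showing delivery trends. Each month's per-consumer use is the
#' effective daily amount times the number of days in that calendar month
#' (capped at the configured use days).
#'
#' The resulting series deliberately cannot be summed: the same individual
#' typically uses the product in many months, so adding monthly headcounts
#' double-counts people. Calling `sum()` (or `total_from_monthly()`) on the
#' series raises an error; to get a period total, aggregate the supply over
#' the whole period and estimate once.
#'
#' @param config a validated product configuration (see [load_config()]);
#'   must be a fast-moving product.
#' @param monthly_supply data frame with columns `month` (`"YYYY-MM"`) and
#'   `grams`, e.g. the `by_month` component of [load_supply_ledger()].
#' @param policy a [rounding_policy()].
#' @return A data frame of class `monthly_reach` with columns `month` and
#'   `total_reach`.
#' @export
monthly_reach <- function(config, monthly_supply, policy = rounding_policy()) {
  config <- validate_config(config)
  policy <- as_rounding_policy(policy)
  if (config$product_type != "fast_moving") {
    abort_validation("monthly_reach supports fast-moving products only")
  }
  stopifnot(is.data.frame(monthly_supply),
            all(c("month", "grams") %in% names(monthly_supply)))
  period <- config$period
  months <- format(period_months(period), "%Y-%m")
  spec <- build_fast_moving_spec(config$use)
  daily <- effective_daily_amount(spec, policy)
  factors <- adjustment_factors(config$supply$quality_factor,
                                config$supply$losses_factor)
  rows <- lapply(months, function(m) {
    g <- sum(monthly_supply$grams[monthly_supply$month == m])
    first <- as.Date(paste0(m, "-01"))
    dim_ <- as.integer(last_day_of_month(first) - first) + 1L
    es <- effective_supply(g * (1 - config$supply$leakage_fraction), factors)
    use <- per_consumer_period_use(daily, dim_, policy)
    data.frame(month = m,
               total_reach = reach_fast_moving(es, use, policy)$total_reach)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("monthly_reach", "data.frame")
  out
}

#' @export
Summary.monthly_reach <- function(..., na.rm = FALSE) {
  if (.Generic == "sum") {
    abort_arithmetic(paste(
      "monthly product reach must not be summed into a period total:",
      "individuals who use the product in several months would be",
      "double-counted. Aggregate supply over the full period and",
      "re-estimate instead."
    ), subclass = "reach_monthly_sum_error")
  }
  x <- list(...)[[1]]
  get(.Generic)(x$total_reach, na.rm = na.rm)
}

#' Guard against summing a monthly reach series
#'
#' Always raises an error: monthly reach headcounts are not additive (see
#' [monthly_reach()]).
#'
#' @param x a `monthly_reach` series.
#' @export
total_from_monthly <- function(x) {
  stopifnot(inherits(x, "monthly_reach"))
  sum(x)
}
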