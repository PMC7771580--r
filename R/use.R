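#' Consumer use pattern for a fast-moving product
#'
#' Describes how much of a fast-moving product one consumer uses: a base
#' daily amount (either measured directly from consumers, the preferred
#' basis, or a recommended portion size), an ordered set of named
#' multiplicative adjustments in \[0, 1\] (e.g. the share of consumption
#' that happens at home, or the share of category consumption that is the
#' target product), a conversion divisor to align consumption units with
#' supply units (e.g. cooked-to-dry mass ratio), and the number of days the
#' product is used in the period.
#'
#' @param base_daily_amount mass (grams) used per consumer per use day,
#'   before adjustments.
#' @param use_days number of use days in the period, or the string
#'   `"period"` meaning every day of the period (daily-use staples); the
#'   string form is resolved against the period by the estimation pipeline.
#' @param amount_basis,frequency_basis `"measured"` (from consumer data) or
#'   `"recommended"` (portion size / recommended frequency).
#' @param multipliers named numeric vector (or list of `{name, value}`
#'   pairs) of proportions in \[0, 1\] applied multiplicatively to the base
#'   amount.
#' @param conversion_divisor positive divisor converting the consumption
#'   basis to the supply basis (default 1).
#' @return An object of class `fast_moving_use`.
#' @examples
#' fast_moving_use(160.3, use_days = "period",
#'                 multipliers = c(at_home = 0.85, product_share = 0.60),
#'                 conversion_divisor = 2.5)
#' @export
fast_moving_use <- function(base_daily_amount, use_days,
                            amount_basis = c("measured", "recommended"),
                            multipliers = numeric(),
                            conversion_divisor = 1,
                            frequency_basis = c("measured", "recommended")) {
  amount_basis <- match.arg(amount_basis)
  frequency_basis <- match.arg(frequency_basis)
  multipliers <- normalize_multipliers(multipliers)
  fc <- fail_collector()
  if (!is_scalar_number(base_daily_amount) || base_daily_amount <= 0) {
    fc$add("base_daily_amount must be a single positive number")
  }
  if (length(multipliers) && any(multipliers < 0 | multipliers > 1)) {
    fc$add("all multipliers must lie in [0, 1]")
  }
  if (!is_scalar_number(conversion_divisor) || conversion_divisor <= 0) {
    fc$add("conversion_divisor must be a single positive number")
  }
  if (!(identical(use_days, "period") ||
        (is_scalar_number(use_days) && use_days > 0))) {
    fc$add("use_days must be a positive number or the string \"period\"")
  }
  fc$raise("invalid fast-moving use spec")
  structure(
    list(base_daily_amount = base_daily_amount, amount_basis = amount_basis,
         multipliers = multipliers, conversion_divisor = conversion_divisor,
         use_days = use_days, frequency_basis = frequency_basis),
    class = "fast_moving_use"
  )
}

normalize_multipliers <- function(m) {
  if (is.null(m)) return(numeric())
  if (is.list(m)) {
    vals <- vapply(m, function(x) as.numeric(x$value), numeric(1))
    names(vals) <- vapply(m, function(x) as.character(x$name), character(1))
    return(vals)
  }
  if (!is.numeric(m)) abort_validation("multipliers must be numeric")
  m
}

#' Consumer use pattern for a durable product
#'
#' A durable good serves one or more users per unit (a single figure, or a
#' weighted household-size distribution) for an average length of use.
#' Together with the period length, the length of use determines turnover:
#' how many units one consumer goes through during the period.
#'
#' @param users_per_unit average number of users per product unit; give
#'   either this or `household_distribution`.
#' @param household_distribution a list of `list(weight =, users =)` pairs
#'   (weights summing to 1) describing disaggregated users-per-unit data,
#'   e.g. 30% of households with 4 users, 50% with 6, 20% with 9.
#' @param length_of_use_days average (`basis = "measured"`) or recommended
#'   (`basis = "recommended"`) length of use of one unit, in days.
#' @param basis `"measured"` or `"recommended"`.
#' @return An object of class `durable_use`.
#' @examples
#' durable_use(users_per_unit = 1, length_of_use_days = 365)
#' @export
durable_use <- function(users_per_unit = NULL, household_distribution = NULL,
                        length_of_use_days,
                        basis = c("measured", "recommended")) {
  basis <- match.arg(basis)
  fc <- fail_collector()
  if (is.null(users_per_unit) == is.null(household_distribution)) {
    fc$add("give exactly one of users_per_unit or household_distribution")
  }
  if (!is.null(users_per_unit) &&
      (!is_scalar_number(users_per_unit) || users_per_unit <= 0)) {
    fc$add("users_per_unit must be a single positive number")
  }
  if (!is.null(household_distribution)) {
    w <- vapply(household_distribution, function(x) as.numeric(x$weight), numeric(1))
    u <- vapply(household_distribution, function(x) as.numeric(x$users), numeric(1))
    if (abs(sum(w) - 1) > 1e-9) {
      fc$add(sprintf("household_distribution weights must sum to 1 (got %.10g)", sum(w)))
    }
    if (any(u <= 0)) fc$add("all household_distribution user counts must be positive")
  }
  if (!is_scalar_number(length_of_use_days) || length_of_use_days <= 0) {
    fc$add("length_of_use_days must be a single positive number")
  }
  fc$raise("invalid durable use spec")
  structure(
    list(users_per_unit = users_per_unit,
         household_distribution = household_distribution,
         length_of_use_days = length_of_use_days, basis = basis),
    class = "durable_use"
  )
}

#' Effective daily amount used per consumer
#'
#' Chains the base daily amount through the named multipliers and the
#' conversion divisor:
#' `base × Π(multipliers) ÷ conversion_divisor`. Under the replication
#' rounding policy the result is rounded to 0.1 g, matching the precision a
#' desk calculation would print.
#'
#' The product of multipliers is order-invariant; multipliers are named only
#' for the assumptions ledger.
#'
#' @param spec a [fast_moving_use()].
#' @param policy a [rounding_policy()].
#' @return Mass per consumer per use day, in grams.
#' @examples
#' spec <- fast_moving_use(160.3, use_days = "period",
#'                         multipliers = c(home = 0.85, share = 0.60),
#'                         conversion_divisor = 2.5)
#' effective_daily_amount(spec, rounding_policy("replication")) # 32.7
#' @export
effective_daily_amount <- function(spec, policy = rounding_policy()) {
  stopifnot(inherits(spec, "fast_moving_use"))
  policy <- as_rounding_policy(policy)
  x <- spec$base_daily_amount * prod(spec$multipliers) / spec$conversion_divisor
  round_daily_grams(x, policy)
}

#' Product use per consumer over the period
#'
#' Multiplies the effective daily amount by the number of use days in the
#' period. Under the replication policy the result is rounded to the
#' nearest gram.
#'
#' @param daily effective daily amount (grams/person/day).
#' @param use_days number of use days in the period.
#' @param policy a [rounding_policy()].
#' @param basis_note free text recording the provenance (measured vs
#'   recommended) of the inputs, kept for the assumptions ledger.
#' @param period_days optional period length; when given, `use_days` must
#'   not exceed it.
#' @return An object of class `per_consumer_use` with `quantity` in grams.
#' @examples
#' per_consumer_period_use(32.7, 819, rounding_policy("replication"))
#' @export
per_consumer_period_use <- function(daily, use_days, policy = rounding_policy(),
                                    basis_note = NULL, period_days = NULL) {
  policy <- as_rounding_policy(policy)
  if (!is_scalar_number(daily) || daily <= 0) {
    abort_validation("daily amount must be a single positive number")
  }
  if (!is_scalar_number(use_days) || use_days <= 0) {
    abort_validation("use_days must be a single positive number")
  }
  if (!is.null(period_days) && use_days > period_days) {
    abort_validation(sprintf(
      "use_days (%g) exceeds the period length (%g days)", use_days, period_days
    ))
  }
  q <- round_period_grams(daily * use_days, policy)
  structure(
    list(quantity = q,
         basis_note = if (is.null(basis_note))
           sprintf("%g g/day x %g use days", daily, use_days) else basis_note),
    class = "per_consumer_use"
  )
}

#' @export
print.per_consumer_use <- function(x, ...) {
  cat(sprintf("<per_consumer_use> %g g per consumer over the period (%s)\n",
              x$quantity, x$basis_note))
  invisible(x)
}

#' Average number of users per product unit
#'
#' Returns the scalar users-per-unit figure, or the weighted average over a
#' household-size distribution when disaggregated data are available. A
#' product intended for individual use has one user per unit; a household
#' product has the average household size in the defined area.
#'
#' @param spec a [durable_use()].
#' @return Average users per unit (a single number).
#' @examples
#' users_per_unit(durable_use(
#'   household_distribution = list(list(weight = 0.3, users = 4),
#'                                 list(weight = 0.5, users = 6),
#'                                 list(weight = 0.2, users = 9)),
#'   length_of_use_days = 3650)) # 6
#' @export
users_per_unit <- function(spec) {
  stopifnot(inherits(spec, "durable_use"))
  if (!is.null(spec$users_per_unit)) return(spec$users_per_unit)
  w <- vapply(spec$household_distribution, function(x) as.numeric(x$weight), numeric(1))
  u <- vapply(spec$household_distribution, function(x) as.numeric(x$users), numeric(1))
  sum(w * u)
}

#' Durable-good turnover: units used per consumer in the period
#'
#' The period length divided by the product's average (or recommended)
#' length of use. When the length of use is at least the period length,
#' turnover is 1: each consumer uses a single unit during the period and
#' product replacement is not an issue. The ratio is returned unrounded;
#' rounding happens only at the headcount stage.
#'
#' @param period_days length of the estimation period, in days.
#' @param length_of_use_days average length of use of one unit, in days.
#' @return Units per consumer over the period, always >= 1.
#' @examples
#' turnover_units(5 * 365, 365) # a menstrual cup replaced yearly: 5
#' turnover_units(365, 3650)    # long-lived product: 1
#' @export
turnover_units <- function(period_days, length_of_use_days) {
  if (!is_scalar_number(period_days) || period_days <= 0 ||
      !is_scalar_number(length_of_use_days) || length_of_use_days <= 0) {
    abort_validation("period_days and length_of_use_days must be positive numbers")
  }
  if (length_of_use_days >= period_days) 1 else period_days / length_of_use_days
}
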