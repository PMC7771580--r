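#' Reach estimation results
#'
#' All reach estimators return a `reach_result`: the total headcount, any
#' per-segment and per-subgroup headcounts, which formula produced it (F1
#' coverage x population; F2 durable; F3 fast-moving), the assumptions
#' ledger accumulated along the way, and the rounding policy used.
#' `total_reach_exact` preserves the unrounded value so that conservation
#' properties (reach x per-consumer use = effective supply) can be checked
#' before integer rounding.
#'
#' @name reach_result
NULL

new_reach_result <- function(total_reach, formula_used,
                             total_reach_exact = total_reach,
                             segment_reach = NULL, subgroup_reach = NULL,
                             assumptions_ledger = empty_ledger(),
                             policy = rounding_policy(),
                             details = list(),
                             check_segments = TRUE) {
  if (!is.null(segment_reach) && check_segments) {
    # each segment is rounded independently, so allow +/-1 per segment
    stopifnot(abs(total_reach - sum(segment_reach)) <= length(segment_reach))
  }
  if (!is.null(subgroup_reach)) {
    stopifnot(all(subgroup_reach <= total_reach))
  }
  structure(
    list(total_reach = total_reach, total_reach_exact = total_reach_exact,
         segment_reach = segment_reach, subgroup_reach = subgroup_reach,
         formula_used = formula_used, assumptions_ledger = assumptions_ledger,
         policy = policy, details = details),
    class = "reach_result"
  )
}

#' @export
print.reach_result <- function(x, ...) {
  cat(sprintf("<reach_result> total reach: %s individuals (%s, %s rounding)\n",
              format(x$total_reach, big.mark = ","), x$formula_used,
              x$policy$mode))
  if (!is.null(x$segment_reach)) {
    cat("  segments:\n")
    for (nm in names(x$segment_reach)) {
      cat(sprintf("    %-24s %s\n", nm,
                  format(x$segment_reach[[nm]], big.mark = ",")))
    }
  }
  if (!is.null(x$subgroup_reach)) {
    cat("  subgroups:\n")
    for (nm in names(x$subgroup_reach)) {
      cat(sprintf("    %-24s %s\n", nm,
                  format(x$subgroup_reach[[nm]], big.mark = ",")))
    }
  }
  if (nrow(x$assumptions_ledger) > 0) {
    cat(sprintf("  assumptions recorded: %d (see $assumptions_ledger)\n",
                nrow(x$assumptions_ledger)))
  }
  invisible(x)
}

# ---- assumptions ledger ----------------------------------------------------

empty_ledger <- function() {
  data.frame(element = character(), measure = character(),
             basis = character(), value = character(),
             stringsAsFactors = FALSE)
}

ledger_entry <- function(element, measure, basis, value) {
  data.frame(element = element, measure = measure, basis = basis,
             value = as.character(value), stringsAsFactors = FALSE)
}

ledger_bind <- function(...) {
  do.call(rbind, Filter(Negate(is.null), list(...)))
}

# ---- coverage route (F1) ---------------------------------------------------

#' Coverage and target-population input
#'
#' Product coverage is the proportion of a population using the product; it
#' may be measured for the total population of the defined area
#' (`scope = "total"`) or for a target group (`scope = "target_group"`).
#' The population figure must have the same scope as the coverage figure.
#'
#' @param coverage proportion in \[0, 1\].
#' @param population person count of the matching population.
#' @param scope `"total"` or `"target_group"`.
#' @return An object of class `coverage_input`.
#' @export
coverage_input <- function(coverage, population,
                           scope = c("total", "target_group")) {
  scope <- match.arg(scope)
  fc <- fail_collector()
  if (!is_proportion(coverage)) fc$add("coverage must lie in [0, 1]")
  if (!is_scalar_number(population) || population < 0) {
    fc$add("population must be a single non-negative number")
  }
  fc$raise("invalid coverage input")
  structure(list(coverage = coverage, population = population, scope = scope),
            class = "coverage_input")
}

#' Reach from measured product coverage (F1)
#'
#' Multiplies product coverage by the number of individuals in the matching
#' population, the direct route to reach when a coverage survey exists.
#'
#' @param input a [coverage_input()].
#' @param policy a [rounding_policy()].
#' @return A [reach_result] with `formula_used = "F1"`.
#' @examples
#' reach_from_coverage(coverage_input(0.5, 1e6))$total_reach # 500,000
#' @export
reach_from_coverage <- function(input, policy = rounding_policy()) {
  stopifnot(inherits(input, "coverage_input"))
  policy <- as_rounding_policy(policy)
  exact <- input$coverage * input$population
  new_reach_result(
    total_reach = round_headcount(exact, policy),
    total_reach_exact = exact,
    formula_used = "F1",
    assumptions_ledger = ledger_entry(
      "H/I coverage x population",
      if (input$scope == "total") "h1 x i1" else "h2 x i2",
      "measured",
      sprintf("coverage %.4g of population %g", input$coverage, input$population)
    ),
    policy = policy
  )
}

#' Coverage implied by a reach estimate
#'
#' Translates an absolute reach headcount back into coverage of a stated
#' population. A ratio above 1 (reach exceeding the population) is returned
#' as computed but flagged via the `"exceeds_population"` attribute; it
#' usually signals leakage outside the defined area or an over-optimistic
#' use assumption.
#'
#' @param reach person count reached.
#' @param population person count of the reference population (> 0).
#' @return Coverage proportion, with logical attribute
#'   `"exceeds_population"`.
#' @examples
#' coverage_from_reach(500000, 1e6) # 0.5
#' @export
coverage_from_reach <- function(reach, population) {
  if (!is_scalar_number(population) || population <= 0) {
    abort_arithmetic("population must be positive to compute coverage")
  }
  if (!is_scalar_number(reach) || reach < 0) {
    abort_validation("reach must be a single non-negative number")
  }
  ratio <- reach / population
  structure(ratio, exceeds_population = ratio > 1)
}

# ---- supply routes (F2, F3) ------------------------------------------------

#' Reach of a fast-moving product (F3)
#'
#' Divides the effective supply by the product use per consumer in the
#' period: the number of individuals for whom that per-consumer quantity was
#' available.
#'
#' @param supply an [effective_supply()] (mass, grams).
#' @param use a [per_consumer_use] from [per_consumer_period_use()].
#' @param policy a [rounding_policy()].
#' @return A [reach_result] with `formula_used = "F3"`.
#' @examples
#' s <- effective_supply(11174.56e6)
#' u <- per_consumer_period_use(32.7, 819, rounding_policy("replication"))
#' reach_fast_moving(s, u, rounding_policy("replication"))$total_reach # 417,257
#' @export
reach_fast_moving <- function(supply, use, policy = rounding_policy()) {
  stopifnot(inherits(supply, "effective_supply"),
            inherits(use, "per_consumer_use"))
  policy <- as_rounding_policy(policy)
  if (use$quantity <= 0) {
    abort_arithmetic("per-consumer use must be positive to compute reach")
  }
  exact <- supply$quantity / use$quantity
  new_reach_result(
    total_reach = round_headcount(exact, policy),
    total_reach_exact = exact,
    formula_used = "F3",
    policy = policy,
    details = list(effective_supply_g = supply$quantity,
                   per_consumer_use_g = use$quantity)
  )
}

#' Reach of a durable product (F2)
#'
#' Each supplied unit serves `users_per_unit` people, but a consumer goes
#' through `turnover` units during the period, so reach is
#' `units x users_per_unit / turnover`. Dividing by turnover is what makes
#' the estimate consistent with the replacement logic: if a consumer uses 5
#' units over the period, 5 units correspond to one consumer, not five.
#'
#' @param units an [effective_supply()] in unit-count form.
#' @param users_per_unit average users per product unit (D).
#' @param turnover units used per consumer in the period (E), from
#'   [turnover_units()]; must be >= 1.
#' @param policy a [rounding_policy()].
#' @return A [reach_result] with `formula_used = "F2"`.
#' @examples
#' cups <- effective_supply(1000, unit_kind = "units")
#' reach_durable(cups, 1, 5)$total_reach # 200
#' @export
reach_durable <- function(units, users_per_unit, turnover,
                          policy = rounding_policy()) {
  stopifnot(inherits(units, "effective_supply"))
  policy <- as_rounding_policy(policy)
  if (!is_scalar_number(users_per_unit) || users_per_unit <= 0) {
    abort_validation("users_per_unit must be a single positive number")
  }
  if (!is_scalar_number(turnover) || turnover < 1) {
    abort_validation("turnover must be >= 1 (one unit per consumer at minimum)")
  }
  exact <- units$quantity * users_per_unit / turnover
  new_reach_result(
    total_reach = round_headcount(exact, policy),
    total_reach_exact = exact,
    formula_used = "F2",
    policy = policy,
    details = list(units = units$quantity, users_per_unit = users_per_unit,
                   turnover = turnover)
  )
}

# ---- segmentation and subgroups --------------------------------------------

#' Define a consumer segment
#'
#' A segment (e.g. repeat vs trial consumers) claims a share of the
#' effective supply and has its own per-consumer use. Shares across a
#' segment set must sum to 1.
#'
#' @param name free-text segment name.
#' @param supply_share proportion of effective supply consumed by the
#'   segment.
#' @param per_consumer_use a [per_consumer_use] for the segment.
#' @return An object of class `consumer_segment`.
#' @export
consumer_segment <- function(name, supply_share, per_consumer_use) {
  fc <- fail_collector()
  if (!is_proportion(supply_share)) fc$add("supply_share must lie in [0, 1]")
  if (!inherits(per_consumer_use, "per_consumer_use") ||
      per_consumer_use$quantity <= 0) {
    fc$add("per_consumer_use must be a positive per_consumer_use object")
  }
  fc$raise(sprintf("invalid consumer segment '%s'", name))
  structure(list(name = name, supply_share = supply_share,
                 per_consumer_use = per_consumer_use),
            class = "consumer_segment")
}

#' Reach across consumer segments with different use patterns
#'
#' Splits the effective supply across segments by their supply shares and
#' divides each segment's supply by that segment's per-consumer use; the
#' total reach is the sum of segment headcounts. Under the replication
#' policy each segment's supply is rounded to 0.01 metric tons before
#' division, matching printed desk arithmetic.
#'
#' @param supply an [effective_supply()].
#' @param segments list of [consumer_segment()]s whose shares sum to 1.
#' @param policy a [rounding_policy()].
#' @return A [reach_result] with per-segment headcounts.
#' @export
segmented_reach <- function(supply, segments, policy = rounding_policy()) {
  stopifnot(inherits(supply, "effective_supply"))
  policy <- as_rounding_policy(policy)
  stopifnot(length(segments) >= 1L,
            all(vapply(segments, inherits, logical(1), "consumer_segment")))
  shares <- vapply(segments, `[[`, numeric(1), "supply_share")
  if (abs(sum(shares) - 1) > 1e-9) {
    abort_validation(sprintf(
      "segment supply shares must sum to 1 (got %.10g)", sum(shares)
    ))
  }
  nms <- vapply(segments, `[[`, character(1), "name")
  if (anyDuplicated(nms)) abort_validation("segment names must be unique")
  seg_exact <- numeric(length(segments))
  seg_reach <- numeric(length(segments))
  seg_supply <- numeric(length(segments))
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    seg_supply[i] <- round_segment_supply_grams(supply$quantity * s$supply_share,
                                                policy)
    seg_exact[i] <- seg_supply[i] / s$per_consumer_use$quantity
    seg_reach[i] <- round_headcount(seg_exact[i], policy)
  }
  names(seg_reach) <- nms
  new_reach_result(
    total_reach = sum(seg_reach),
    total_reach_exact = sum(seg_exact),
    segment_reach = seg_reach,
    formula_used = "F3",
    policy = policy,
    details = list(
      effective_supply_g = supply$quantity,
      segment_supply_g = stats::setNames(seg_supply, nms),
      segment_use_g = stats::setNames(
        vapply(segments, function(s) s$per_consumer_use$quantity, numeric(1)), nms)
    )
  )
}

#' Define a population subgroup
#'
#' Subgroups (e.g. women of reproductive age, young children, lower
#' socio-economic classes) are fractions of the total population; they may
#' overlap, so fractions need not sum to 1.
#'
#' @param name free-text subgroup name.
#' @param population_fraction proportion of the population in the subgroup.
#' @return An object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(name, population_fraction) {
  if (!is_proportion(population_fraction)) {
    abort_validation(sprintf(
      "subgroup '%s': population_fraction must lie in [0, 1]", name
    ))
  }
  structure(list(name = name, population_fraction = population_fraction),
            class = "subgroup_spec")
}

#' Allocate total reach to population subgroups
#'
#' Assuming homogeneous use across subgroups (an assumption recorded in the
#' ledger of any result that carries subgroups), each subgroup's reach is
#' the total reach times the subgroup's population fraction.
#'
#' @param total total reach headcount.
#' @param subgroups list of [subgroup_spec()]s.
#' @param policy a [rounding_policy()].
#' @return Named numeric vector of subgroup headcounts.
#' @examples
#' subgroup_reach(2365712, list(subgroup_spec("women_15_49", 0.2814)))
#' @export
subgroup_reach <- function(total, subgroups, policy = rounding_policy()) {
  policy <- as_rounding_policy(policy)
  if (!is_scalar_number(total) || total < 0) {
    abort_validation("total reach must be a single non-negative number")
  }
  stopifnot(all(vapply(subgroups, inherits, logical(1), "subgroup_spec")))
  out <- vapply(subgroups, function(s) {
    round_headcount(total * s$population_fraction, policy)
  }, numeric(1))
  names(out) <- vapply(subgroups, `[[`, character(1), "name")
  out
}

# ---- razor-and-blade -------------------------------------------------------

#' Combine razor (durable) and blade (consumable) reach estimates
#'
#' A razor-and-blade product pairs a durable component with a consumable
#' refill; each is estimated with its own model (F2 for the razor, F3 for
#' the blades). When only one component's data exist, that component's
#' estimate stands for the combined product. When both exist, both are
#' reported and the minimum is taken as the combined estimate: a consumer
#' must hold the durable *and* buy refills, so the smaller headcount is the
#' conservative bound on people using the complete product.
#'
#' @param razor,blade [reach_result]s for the components, or `NULL` when a
#'   component's data are unavailable (at least one must be present).
#' @return A [reach_result] whose `segment_reach` holds the available
#'   component totals and whose `formula_used` is that of the binding
#'   (smaller) component.
#' @export
razor_blade_reach <- function(razor = NULL, blade = NULL) {
  if (is.null(razor) && is.null(blade)) {
    abort_validation("razor_blade_reach needs at least one component estimate")
  }
  comps <- Filter(Negate(is.null), list(razor = razor, blade = blade))
  stopifnot(all(vapply(comps, inherits, logical(1), "reach_result")))
  totals <- vapply(comps, `[[`, numeric(1), "total_reach")
  binding <- names(comps)[which.min(totals)]
  ledger <- do.call(ledger_bind, lapply(comps, `[[`, "assumptions_ledger"))
  if (length(comps) == 2L) {
    ledger <- ledger_bind(ledger, ledger_entry(
      "razor-blade combination", "min(razor, blade)", "model rule",
      sprintf("binding component: %s", binding)
    ))
  }
  new_reach_result(
    total_reach = min(totals),
    total_reach_exact = min(vapply(comps, `[[`, numeric(1), "total_reach_exact")),
    segment_reach = totals,
    formula_used = comps[[binding]]$formula_used,
    assumptions_ledger = ledger,
    policy = comps[[binding]]$policy,
    details = list(components = comps),
    check_segments = FALSE  # components are alternative estimates, not additive
  )
}
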