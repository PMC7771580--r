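#' Estimate product reach from a configuration
#'
#' Runs the full estimation pipeline for one product configuration:
#'
#' 1. the period is resolved to a day count;
#' 2. supply inputs are converted to effective supply (total supply x
#'    quality factor x losses factor, net of leakage);
#' 3. the per-consumer use is computed from the use pattern (fast-moving:
#'    effective daily amount x use days; durable: users per unit and
#'    turnover);
#' 4. reach is computed with the matching formula (F3 fast-moving, F2
#'    durable, component-wise for razor-and-blade), per consumer segment
#'    when segments are configured;
#' 5. subgroup headcounts are allocated under the homogeneous-use
#'    assumption.
#'
#' When the configuration carries no supply block but has coverage data,
#' the coverage route (F1) is used instead.
#'
#' @param config a `product_config` (from [load_config()] /
#'   [validate_config()], or a plain list which will be validated).
#' @param policy a [rounding_policy()] (or its mode string).
#' @return A [reach_result].
#' @examples
#' cfg <- load_config(system.file("extdata", "brazil_fortified_rice.yaml",
#'                                package = "reachcalc"))
#' estimate_reach(cfg, "replication")
#' @export
estimate_reach <- function(config, policy = rounding_policy()) {
  config <- validate_config(config)
  policy <- as_rounding_policy(policy)
  coverage_only <- is.null(config$supply) && is.null(config$components) &&
    !is.null(config$coverage)
  res <- if (coverage_only) {
    reach_from_coverage(config$coverage, policy)
  } else switch(config$product_type,
    fast_moving = estimate_fast_moving(config, policy),
    durable = estimate_durable(config, policy),
    razor_blade = estimate_razor_blade(config, policy)
  )
  if (!is.null(config$subgroups)) {
    subs <- lapply(config$subgroups, function(s)
      subgroup_spec(s$name, s$population_fraction))
    res$subgroup_reach <- subgroup_reach(res$total_reach, subs, policy)
    res$assumptions_ledger <- ledger_bind(
      res$assumptions_ledger,
      ledger_entry("subgroup allocation", "population fractions", "assumption",
                   "homogeneous product use across subgroups")
    )
  }
  res$assumptions_ledger <- ledger_bind(attr(config, "assumptions_ledger"),
                                        res$assumptions_ledger)
  res
}

resolve_use_days <- function(use_days, period_days) {
  if (identical(use_days, "period")) period_days else use_days
}

build_fast_moving_spec <- function(use) {
  fast_moving_use(use$base_daily_amount,
                  use_days = use$use_days,
                  amount_basis = use$amount_basis,
                  multipliers = use$multipliers,
                  conversion_divisor = use$conversion_divisor,
                  frequency_basis = use$frequency_basis)
}

build_effective_supply <- function(supply, period, area, unit_kind) {
  si <- supply_inputs(mode = supply$mode,
                      sales_volume = supply$sales_volume,
                      production = supply$production,
                      imports = if (is.null(supply$imports)) 0 else supply$imports,
                      exports = if (is.null(supply$exports)) 0 else supply$exports,
                      leakage_fraction = supply$leakage_fraction,
                      unit = supply$unit)
  effective_supply(total_supply(si),
                   adjustment_factors(supply$quality_factor,
                                      supply$losses_factor),
                   period = period, area_label = area, unit_kind = unit_kind)
}

estimate_fast_moving <- function(config, policy,
                                 supply = config$supply, use = config$use) {
  period <- config$period
  pd <- period_length_days(period)
  es <- build_effective_supply(supply, period, config$area, "mass")
  spec <- build_fast_moving_spec(use)
  daily <- effective_daily_amount(spec, policy)
  led <- ledger_bind(
    ledger_entry("F use amount",
                 if (spec$amount_basis == "measured") "f1" else "f2",
                 spec$amount_basis,
                 sprintf("%g g/day effective (base %g)", daily,
                         spec$base_daily_amount)),
    ledger_entry("G use frequency",
                 if (spec$frequency_basis == "measured") "g1" else "g2",
                 spec$frequency_basis,
                 sprintf("use_days = %s",
                         if (identical(spec$use_days, "period"))
                           sprintf("period (%d)", pd) else spec$use_days))
  )
  if (!is.null(config$segments)) {
    segs <- lapply(config$segments, function(s) {
      days <- resolve_use_days(s$use_days, pd)
      consumer_segment(s$name, s$supply_share,
                       per_consumer_period_use(daily, days, policy,
                                               period_days = pd))
    })
    res <- segmented_reach(es, segs, policy)
  } else {
    use_days <- resolve_use_days(spec$use_days, pd)
    pcu <- per_consumer_period_use(daily, use_days, policy, period_days = pd)
    res <- reach_fast_moving(es, pcu, policy)
  }
  res$assumptions_ledger <- ledger_bind(res$assumptions_ledger, led)
  res
}

estimate_durable <- function(config, policy,
                             supply = config$supply, use = config$use) {
  period <- config$period
  pd <- period_length_days(period)
  es <- build_effective_supply(supply, period, config$area, "units")
  spec <- durable_use(users_per_unit = use$users_per_unit,
                      household_distribution = use$household_distribution,
                      length_of_use_days = use$length_of_use_days,
                      basis = use$basis)
  d <- users_per_unit(spec)
  e <- turnover_units(pd, spec$length_of_use_days)
  res <- reach_durable(es, d, e, policy)
  res$assumptions_ledger <- ledger_bind(
    res$assumptions_ledger,
    ledger_entry("D users per unit", "d1",
                 if (is.null(use$users_per_unit)) "distribution" else "scalar",
                 sprintf("%g users/unit", d)),
    ledger_entry("E turnover",
                 if (spec$basis == "measured") "e1" else "e2",
                 spec$basis,
                 sprintf("%g units/consumer over %d days", e, pd))
  )
  res
}

estimate_razor_blade <- function(config, policy) {
  comps <- config$components
  razor <- blade <- NULL
  sub <- function(component, type) {
    c2 <- list(product_name = config$product_name, product_type = type,
               period = list(start = format(config$period$start, "%Y-%m"),
                             end = format(config$period$end, "%Y-%m")),
               area = config$area,
               supply = component$supply, use = component$use)
    estimate_reach(validate_config(c2), policy)
  }
  if (!is.null(comps$razor)) razor <- sub(comps$razor, "durable")
  if (!is.null(comps$blade)) blade <- sub(comps$blade, "fast_moving")
  razor_blade_reach(razor, blade)
}

#' Full report bundle: estimate, scenarios, triangulation, provenance
#'
#' Runs [estimate_reach()] and, when the inputs allow, adds a scenario range
#' ([run_scenarios()]) and a triangulation of the supply-based estimate
#' against the coverage-based one (both routes must be computable: supply +
#' use and coverage + population). Provenance records the config file hash
#' (when loaded from a file), the rounding policy, and the package version.
#'
#' @param config a `product_config`.
#' @param policy a [rounding_policy()].
#' @param scenarios optional list of [scenario_spec()]s (>= 2) for a
#'   scenario range.
#' @return A list of class `report_bundle` with elements `reach`,
#'   `scenario_range` (or `NULL`), `triangulation` (or `NULL`), and
#'   `provenance`.
#' @export
report_bundle <- function(config, policy = rounding_policy(),
                          scenarios = NULL) {
  config <- validate_config(config)
  policy <- as_rounding_policy(policy)
  reach <- estimate_reach(config, policy)
  range <- if (!is.null(scenarios)) run_scenarios(config, scenarios, policy)
  tri <- NULL
  has_supply <- !is.null(config$supply) || !is.null(config$components)
  if (!is.null(config$coverage) && has_supply && reach$formula_used != "F1") {
    cov_reach <- reach_from_coverage(config$coverage, policy)
    tri <- list(coverage_based_reach = cov_reach$total_reach,
                supply_based_reach = reach$total_reach,
                ratio_supply_to_coverage =
                  reach$total_reach / cov_reach$total_reach)
  }
  path <- attr(config, "config_path")
  prov <- list(
    config_hash = if (is.null(path)) NA_character_
                  else unname(tools::md5sum(path)),
    policy = policy$mode,
    tool_version = as.character(utils::packageVersion("reachcalc"))
  )
  structure(list(reach = reach, scenario_range = range, triangulation = tri,
                 provenance = prov, product_name = config$product_name),
            class = "report_bundle")
}
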