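#' Define a named scenario as a set of config overrides
#'
#' A scenario re-runs the estimate with some configuration fields replaced,
#' e.g. the conservative scenario of a fortified staple assumes consumption
#' at the recommended quantity every day of the period, while a trial-only
#' scenario assumes one use day. Override paths are dot-separated config
#' paths such as `"use.use_days"` or `"supply.quality_factor"` and must
#' exist in the (validated) base configuration.
#'
#' @param name free-text scenario name; reports always carry the name so
#'   the direction of each bound is unambiguous.
#' @param overrides named list mapping config paths to replacement values.
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("recommended_daily_use", list("use.use_days" = 365))
#' @export
scenario_spec <- function(name, overrides) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_validation("scenario name must be a non-empty string")
  }
  if (!is.list(overrides) || length(overrides) == 0L ||
      is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
    abort_validation("overrides must be a non-empty named list of path = value")
  }
  structure(list(name = name, overrides = overrides), class = "scenario_spec")
}

split_path <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

path_exists <- function(x, keys) {
  for (k in keys) {
    if (!is.list(x) || !k %in% names(x)) return(FALSE)
    x <- x[[k]]
  }
  TRUE
}

set_path <- function(x, keys, value) {
  if (length(keys) == 1L) {
    x[[keys]] <- value
    return(x)
  }
  x[[keys[1L]]] <- set_path(x[[keys[1L]]], keys[-1L], value)
  x
}

# Applies overrides to a validated config and re-validates, so overridden
# values pass the same field checks as base values.
apply_overrides <- function(config, overrides) {
  config <- validate_config(config)
  base <- unclass(config)
  attributes(base)[c("assumptions_ledger", "config_path")] <- NULL
  base$period <- list(start = format(config$period$start, "%Y-%m"),
                      end = format(config$period$end, "%Y-%m"),
                      label = config$period$label)
  for (path in names(overrides)) {
    keys <- split_path(path)
    if (!path_exists(base, keys)) {
      abort_validation(sprintf("override path '%s' does not exist in the base config",
                               path))
    }
    base <- set_path(base, keys, overrides[[path]])
  }
  validate_config(base)
}

#' Best/worst-case reach bounds over labelled scenarios
#'
#' Runs the reach estimate once per scenario (each scenario applying its
#' overrides to a copy of the base configuration) and reports the range of
#' totals: the low and high reach and which named scenario produced each.
#' Scenario names, not bare "best/worst" labels, identify the bounds,
#' because the direction is not fixed — assuming a *higher* per-consumer
#' use yields a *lower* (conservative) reach estimate.
#'
#' @param base_config a `product_config`.
#' @param scenarios list of at least two [scenario_spec()]s.
#' @param policy a [rounding_policy()].
#' @return An object of class `scenario_range` with `low_reach`,
#'   `high_reach`, `low_scenario`, `high_scenario`, and `per_scenario` (a
#'   named list of [reach_result]s).
#' @export
run_scenarios <- function(base_config, scenarios, policy = rounding_policy()) {
  base_config <- validate_config(base_config)
  policy <- as_rounding_policy(policy)
  if (!is.list(scenarios) || length(scenarios) < 2L ||
      !all(vapply(scenarios, inherits, logical(1), "scenario_spec"))) {
    abort_validation("run_scenarios needs a list of >= 2 scenario_spec objects")
  }
  nms <- vapply(scenarios, `[[`, character(1), "name")
  if (anyDuplicated(nms)) abort_validation("scenario names must be unique")
  per <- lapply(scenarios, function(sc) {
    estimate_reach(apply_overrides(base_config, sc$overrides), policy)
  })
  names(per) <- nms
  totals <- vapply(per, `[[`, numeric(1), "total_reach")
  structure(
    list(low_reach = min(totals), high_reach = max(totals),
         low_scenario = nms[which.min(totals)],
         high_scenario = nms[which.max(totals)],
         per_scenario = per),
    class = "scenario_range"
  )
}

#' @export
print.scenario_range <- function(x, ...) {
  cat(sprintf("<scenario_range> %s .. %s individuals\n",
              format(x$low_reach, big.mark = ","),
              format(x$high_reach, big.mark = ",")))
  cat(sprintf("  low:  %s\n  high: %s\n", x$low_scenario, x$high_scenario))
  invisible(x)
}

#' One-parameter sensitivity sweep
#'
#' Re-estimates reach for each value of a single configuration field,
#' leaving the rest of the base configuration unchanged. Rows are returned
#' in input order.
#'
#' @param base_config a `product_config`.
#' @param path dot-separated config path (e.g. `"supply.quality_factor"`).
#' @param values vector (or list) of replacement values, each valid for the
#'   field at `path`.
#' @param policy a [rounding_policy()].
#' @return A data frame with columns `value` and `total_reach`.
#' @examples
#' cfg <- load_config(system.file("extdata", "brazil_fortified_rice.yaml",
#'                                package = "reachcalc"))
#' sensitivity_sweep(cfg, "supply.quality_factor", c(1, 0.9, 0.8))
#' @export
sensitivity_sweep <- function(base_config, path, values,
                              policy = rounding_policy()) {
  base_config <- validate_config(base_config)
  policy <- as_rounding_policy(policy)
  if (length(values) < 1L) abort_validation("values must be non-empty")
  values <- as.list(values)
  reach <- vapply(values, function(v) {
    ov <- stats::setNames(list(v), path)
    estimate_reach(apply_overrides(base_config, ov), policy)$total_reach
  }, numeric(1))
  value_col <- if (all(vapply(values, is.numeric, logical(1)))) {
    vapply(values, as.numeric, numeric(1))
  } else {
    vapply(values, function(v) paste(format(v), collapse = ","), character(1))
  }
  data.frame(value = value_col, total_reach = reach)
}
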