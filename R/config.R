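#' Load a product configuration file
#'
#' Reads a YAML or JSON configuration describing one product: its type
#' (fast-moving, durable, or razor-and-blade), the defined period and area,
#' supply inputs with adjustment factors, the consumer use pattern, and
#' optional consumer segments, population subgroups, and coverage data. The
#' configuration is fully validated ([validate_config()]); every default
#' applied (e.g. a quality factor omitted and set to 1) is recorded in the
#' assumptions ledger attached to the returned object.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `product_config` (a list) with attribute
#'   `assumptions_ledger` (a data frame) and `config_path`.
#' @examples
#' cfg <- load_config(system.file("extdata", "brazil_fortified_rice.yaml",
#'                                package = "reachcalc"))
#' cfg$supply$sales_volume
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("config file not found: %s", path))
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- validate_config(raw)
  attr(cfg, "config_path") <- path
  cfg
}

#' Validate a product configuration
#'
#' Checks a configuration list against the model's schema, applies
#' documented defaults (adjustment factors 1, leakage 0, imports/exports 0,
#' conversion divisor 1, measurement bases `"measured"`), and reports
#' *all* failures at once. Defaults applied are recorded in the
#' `assumptions_ledger` attribute so that every assumption feeding an
#' estimate is explicit and reportable.
#'
#' @param config a configuration list (e.g. from [load_config()] or built
#'   in R). Already-validated configs pass through unchanged.
#' @return The validated config, classed `product_config`, with attributes
#'   `assumptions_ledger`.
#' @export
validate_config <- function(config) {
  if (inherits(config, "product_config")) return(config)
  if (!is.list(config)) abort_validation("config must be a list")
  fc <- fail_collector()
  ledger <- empty_ledger()
  note_default <- function(element, measure, value) {
    ledger <<- ledger_bind(ledger, ledger_entry(element, measure, "default", value))
  }

  if (is.null(config$product_name) || !nzchar(as.character(config$product_name)[1])) {
    fc$add("product_name is required")
  }
  if (is.null(config$product_type) ||
      !config$product_type %in% c("fast_moving", "durable", "razor_blade")) {
    fc$add("product_type must be one of fast_moving, durable, razor_blade")
    fc$raise("invalid product configuration")
  }

  # -- period
  if (is.null(config$period) || is.null(config$period$start) ||
      is.null(config$period$end)) {
    fc$add("period with start and end ('YYYY-MM') is required")
  } else {
    config$period <- tryCatch(
      reach_period(config$period$start, config$period$end, config$period$label),
      error = function(e) { fc$add(conditionMessage(e)); NULL }
    )
  }

  if (config$product_type == "razor_blade") {
    config <- validate_razor_blade(config, fc, note_default)
  } else if (is.null(config$supply) && !is.null(config$coverage)) {
    # coverage-only configuration: estimated via the F1 route
  } else {
    config$supply <- validate_supply_block(config$supply, fc, note_default)
    config$use <- validate_use_block(config$use, config$product_type, fc,
                                     note_default)
  }

  # -- segments (fast-moving only)
  if (!is.null(config$segments)) {
    if (config$product_type != "fast_moving") {
      fc$add("segments are only supported for fast_moving products")
    } else {
      shares <- vapply(config$segments, function(s) {
        if (is.null(s$supply_share) || !is_proportion(s$supply_share)) {
          fc$add(sprintf("segment '%s': supply_share must lie in [0, 1]",
                         if (is.null(s$name)) "?" else s$name))
          return(NA_real_)
        }
        s$supply_share
      }, numeric(1))
      if (!anyNA(shares) && abs(sum(shares) - 1) > 1e-9) {
        fc$add(sprintf("segment supply shares must sum to 1 (got %.10g)",
                       sum(shares)))
      }
      for (s in config$segments) {
        if (is.null(s$name)) fc$add("every segment needs a name")
        if (is.null(s$use_days)) {
          fc$add(sprintf("segment '%s': use_days is required", s$name))
        } else if (!identical(s$use_days, "period") &&
                   !(is_scalar_number(s$use_days) && s$use_days > 0)) {
          fc$add(sprintf("segment '%s': use_days must be positive or \"period\"",
                         s$name))
        }
      }
    }
  }

  # -- subgroups (overlapping groups allowed; no sum-to-1 check)
  if (!is.null(config$subgroups)) {
    for (s in config$subgroups) {
      if (is.null(s$name) || is.null(s$population_fraction) ||
          !is_proportion(s$population_fraction)) {
        fc$add(sprintf(
          "subgroup '%s': population_fraction must lie in [0, 1]",
          if (is.null(s$name)) "?" else s$name))
      }
    }
  }

  # -- coverage (optional; enables F1 estimation and triangulation)
  if (!is.null(config$coverage)) {
    cv <- config$coverage
    if (is.null(cv$scope)) {
      cv$scope <- "total"
      note_default("H/I scope", "h1/i1", "total")
    }
    config$coverage <- tryCatch(
      coverage_input(cv$coverage, cv$population, cv$scope),
      error = function(e) { fc$add(conditionMessage(e)); NULL }
    )
  }

  # -- use_days within period
  if (!is.null(config$period) && inherits(config$period, "reach_period")) {
    pd <- period_length_days(config$period)
    check_days <- function(d, where) {
      if (is_scalar_number(d) && d > pd) {
        fc$add(sprintf("%s: use_days (%g) exceeds the period length (%d days)",
                       where, d, pd))
      }
    }
    if (!is.null(config$use$use_days)) check_days(config$use$use_days, "use")
    for (s in config$segments) check_days(s$use_days, sprintf("segment '%s'", s$name))
  }

  fc$raise("invalid product configuration")
  structure(config, class = "product_config", assumptions_ledger = ledger)
}

validate_supply_block <- function(supply, fc, note_default, where = "supply") {
  if (is.null(supply)) {
    fc$add(sprintf("%s block is required", where))
    return(NULL)
  }
  if (is.null(supply$mode)) {
    supply$mode <- if (!is.null(supply$sales_volume)) "sales_distribution"
                   else "production_flows"
  }
  if (is.null(supply$unit)) {
    fc$add(sprintf("%s: unit is required (grams|kilograms|metric_tons|units)", where))
  } else if (!supply$unit %in% SUPPLY_UNITS) {
    fc$add(sprintf("%s: unknown unit '%s'", where, supply$unit))
  }
  for (f in c("quality_factor", "losses_factor")) {
    if (is.null(supply[[f]])) {
      supply[[f]] <- 1
      note_default(sprintf("%s adjustment", where),
                   if (f == "quality_factor") "b1" else "c1",
                   sprintf("%s defaulted to 1 (no loss assumed)", f))
    } else if (!is_proportion(supply[[f]])) {
      fc$add(sprintf("%s: %s must lie in [0, 1]", where, f))
      supply[[f]] <- NULL
    }
  }
  if (is.null(supply$leakage_fraction)) {
    supply$leakage_fraction <- 0
    note_default(sprintf("%s leakage", where), "a1/a2 adjustment",
                 "leakage_fraction defaulted to 0 (all supply stays in area)")
  } else if (!is_proportion(supply$leakage_fraction)) {
    fc$add(sprintf("%s: leakage_fraction must lie in [0, 1]", where))
  }
  mode_ok <- supply$mode %in% c("sales_distribution", "production_flows")
  if (!mode_ok) {
    fc$add(sprintf("%s: mode must be sales_distribution or production_flows", where))
    return(supply)
  }
  if (supply$mode == "sales_distribution") {
    if (is.null(supply$sales_volume) ||
        !is_scalar_number(supply$sales_volume) || supply$sales_volume < 0) {
      fc$add(sprintf("%s: sales_volume (non-negative number) is required", where))
    }
  } else {
    if (is.null(supply$production) ||
        !is_scalar_number(supply$production) || supply$production < 0) {
      fc$add(sprintf("%s: production (non-negative number) is required", where))
    }
    for (f in c("imports", "exports")) {
      if (is.null(supply[[f]])) {
        supply[[f]] <- 0
        note_default(sprintf("%s flows", where), "a2",
                     sprintf("%s defaulted to 0", f))
      } else if (!is_scalar_number(supply[[f]]) || supply[[f]] < 0) {
        fc$add(sprintf("%s: %s must be a non-negative number", where, f))
      }
    }
  }
  supply
}

validate_use_block <- function(use, product_type, fc, note_default,
                               where = "use") {
  if (is.null(use)) {
    fc$add(sprintf("%s block is required", where))
    return(NULL)
  }
  if (is.null(use$type)) use$type <- product_type
  if (!identical(use$type, product_type)) {
    fc$add(sprintf("%s: use type '%s' does not match product_type '%s'",
                   where, use$type, product_type))
    return(use)
  }
  if (product_type == "fast_moving") {
    if (is.null(use$amount_basis)) {
      use$amount_basis <- "measured"
      note_default(sprintf("%s amount basis", where), "f1", "measured")
    }
    if (is.null(use$frequency_basis)) {
      use$frequency_basis <- "measured"
      note_default(sprintf("%s frequency basis", where), "g1", "measured")
    }
    if (is.null(use$conversion_divisor)) {
      use$conversion_divisor <- 1
      note_default(sprintf("%s conversion", where), "f1/f2",
                   "conversion_divisor defaulted to 1")
    }
    if (is.null(use$use_days)) {
      fc$add(sprintf("%s: use_days (number or \"period\") is required", where))
    }
    check <- tryCatch({
      fast_moving_use(use$base_daily_amount,
                      use_days = if (is.null(use$use_days)) 1 else use$use_days,
                      amount_basis = use$amount_basis,
                      multipliers = use$multipliers,
                      conversion_divisor = use$conversion_divisor,
                      frequency_basis = use$frequency_basis)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(check)) fc$add(sprintf("%s: %s", where, check))
  } else {
    if (is.null(use$basis)) {
      use$basis <- "measured"
      note_default(sprintf("%s length-of-use basis", where), "e1", "measured")
    }
    check <- tryCatch({
      durable_use(users_per_unit = use$users_per_unit,
                  household_distribution = use$household_distribution,
                  length_of_use_days =
                    if (is.null(use$length_of_use_days)) -1
                    else use$length_of_use_days,
                  basis = use$basis)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(check)) fc$add(sprintf("%s: %s", where, check))
  }
  use
}

validate_razor_blade <- function(config, fc, note_default) {
  comps <- config$components
  if (is.null(comps) || (is.null(comps$razor) && is.null(comps$blade))) {
    fc$add("razor_blade products need a components block with razor and/or blade")
    return(config)
  }
  extra <- setdiff(names(comps), c("razor", "blade"))
  if (length(extra)) {
    fc$add(sprintf("unknown razor_blade component(s): %s",
                   paste(extra, collapse = ", ")))
  }
  if (!is.null(comps$razor)) {
    comps$razor$supply <- validate_supply_block(comps$razor$supply, fc,
                                                note_default, "razor supply")
    comps$razor$use <- validate_use_block(comps$razor$use, "durable", fc,
                                          note_default, "razor use")
  }
  if (!is.null(comps$blade)) {
    comps$blade$supply <- validate_supply_block(comps$blade$supply, fc,
                                                note_default, "blade supply")
    comps$blade$use <- validate_use_block(comps$blade$use, "fast_moving", fc,
                                          note_default, "blade use")
  }
  config$components <- comps
  config
}

#' @export
print.product_config <- function(x, ...) {
  cat(sprintf("<product_config> %s (%s)\n", x$product_name, x$product_type))
  if (inherits(x$period, "reach_period")) {
    cat("  period:", x$period$label, "\n")
  }
  led <- attr(x, "assumptions_ledger")
  if (!is.null(led) && nrow(led) > 0) {
    cat(sprintf("  defaults applied: %d (see attr(, \"assumptions_ledger\"))\n",
                nrow(led)))
  }
  invisible(x)
}
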