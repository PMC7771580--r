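#' Describe product supply over the defined period
#'
#' Total supply of a product in the defined area can be measured in one of
#' two ways: directly, as the sales/dispatch/distribution volume
#' (`mode = "sales_distribution"`), or indirectly from production flows as
#' production − exports + imports (`mode = "production_flows"`). Either
#' measure may be shrunk by a leakage fraction accounting for supply that
#' leaves the defined area (or, equivalently, excess supply never purchased).
#'
#' @param mode `"sales_distribution"` or `"production_flows"`.
#' @param sales_volume sales/distribution volume (required in sales mode).
#' @param production,imports,exports production-flow quantities (production
#'   required in flows mode; imports/exports default to 0).
#' @param leakage_fraction proportion in \[0, 1\] of supply leaving the
#'   defined area; default 0.
#' @param unit unit of all quantities: `"grams"`, `"kilograms"`,
#'   `"metric_tons"` for mass, or `"units"` for durable-good counts.
#' @return An object of class `supply_inputs`.
#' @examples
#' supply_inputs("sales_distribution", sales_volume = 11174.56,
#'               unit = "metric_tons")
#' @export
supply_inputs <- function(mode = c("sales_distribution", "production_flows"),
                          sales_volume = NULL, production = NULL,
                          imports = 0, exports = 0,
                          leakage_fraction = 0,
                          unit = c("metric_tons", "grams", "kilograms", "units")) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  fc <- fail_collector()
  if (mode == "sales_distribution") {
    if (is.null(sales_volume)) fc$add("sales_volume is required in sales_distribution mode")
    if (!is.null(production)) fc$add("production is not a sales_distribution field")
  } else {
    if (is.null(production)) fc$add("production is required in production_flows mode")
    if (!is.null(sales_volume)) fc$add("sales_volume is not a production_flows field")
  }
  for (nm in c("sales_volume", "production", "imports", "exports")) {
    v <- get(nm)
    if (!is.null(v) && (!is_scalar_number(v) || v < 0)) {
      fc$add(sprintf("%s must be a single non-negative number", nm))
    }
  }
  if (!is_proportion(leakage_fraction)) {
    fc$add("leakage_fraction must lie in [0, 1]")
  }
  fc$raise("invalid supply inputs")
  structure(
    list(mode = mode, sales_volume = sales_volume, production = production,
         imports = imports, exports = exports,
         leakage_fraction = leakage_fraction, unit = unit),
    class = "supply_inputs"
  )
}

#' Quality and post-production loss adjustment factors
#'
#' Both factors are proportions in \[0, 1\] where 1 means no loss: the
#' quality factor is the fraction of supplied product meeting specification,
#' and the losses factor is the fraction surviving post-production
#' transport/storage losses. Both default to 1 (the reach-maximising
#' assumption used when no monitoring data suggest otherwise).
#'
#' @param quality_factor,losses_factor proportions in \[0, 1\].
#' @return An object of class `adjustment_factors`.
#' @export
adjustment_factors <- function(quality_factor = 1, losses_factor = 1) {
  fc <- fail_collector()
  if (!is_proportion(quality_factor)) fc$add("quality_factor must lie in [0, 1]")
  if (!is_proportion(losses_factor)) fc$add("losses_factor must lie in [0, 1]")
  fc$raise("invalid adjustment factors")
  structure(list(quality_factor = quality_factor, losses_factor = losses_factor),
            class = "adjustment_factors")
}

#' Total product supply in canonical units
#'
#' Applies the mode-specific supply formula and the leakage fraction, and
#' converts to canonical internal units (grams for mass, counts for
#' durables):
#' sales mode gives `sales_volume × (1 − leakage)`, flows mode gives
#' `(production − exports + imports) × (1 − leakage)`.
#'
#' @param inputs a [supply_inputs()].
#' @return Total supply in grams (or unit count), a single number.
#' @examples
#' total_supply(supply_inputs("sales_distribution", sales_volume = 11174.56,
#'                            unit = "metric_tons")) # 11,174,560,000 g
#' @export
total_supply <- function(inputs) {
  stopifnot(inherits(inputs, "supply_inputs"))
  raw <- if (inputs$mode == "sales_distribution") {
    inputs$sales_volume
  } else {
    net <- inputs$production - inputs$exports + inputs$imports
    if (net < 0) {
      abort_arithmetic(sprintf(
        "inconsistent production flows: exports (%g) exceed production + imports (%g)",
        inputs$exports, inputs$production + inputs$imports
      ))
    }
    net
  }
  to_grams(raw * (1 - inputs$leakage_fraction), inputs$unit)
}

#' Effective supply: quantity of high-quality product available to consumers
#'
#' Multiplies total supply by the quality adjustment factor and the
#' post-production losses adjustment factor, giving the quantity of product
#' actually available to consumers at the desired quality over the defined
#' period.
#'
#' @param total total supply in canonical units (grams or unit count), as
#'   returned by [total_supply()].
#' @param factors an [adjustment_factors()]; defaults to no adjustment.
#' @param period optional [reach_period()] carried along for reporting.
#' @param area_label optional free-text area description.
#' @param unit_kind `"mass"` (grams) or `"units"` (durable-good counts).
#' @return An object of class `effective_supply` with field `quantity` in
#'   canonical units.
#' @examples
#' effective_supply(1000, adjustment_factors(0.9, 0.8))$quantity # 720
#' @export
effective_supply <- function(total, factors = adjustment_factors(),
                             period = NULL, area_label = NULL,
                             unit_kind = c("mass", "units")) {
  unit_kind <- match.arg(unit_kind)
  stopifnot(inherits(factors, "adjustment_factors"))
  if (!is_scalar_number(total) || total < 0) {
    abort_validation("total supply must be a single non-negative number")
  }
  q <- total * factors$quality_factor * factors$losses_factor
  structure(
    list(quantity = q, total_before_adjustment = total, factors = factors,
         period = period, area_label = area_label, unit_kind = unit_kind),
    class = "effective_supply"
  )
}

#' @export
print.effective_supply <- function(x, ...) {
  if (x$unit_kind == "mass") {
    cat(sprintf("<effective_supply> %.2f MT", x$quantity / GRAMS_PER_MT))
  } else {
    cat(sprintf("<effective_supply> %g units", x$quantity))
  }
  if (!is.null(x$area_label)) cat(" in", x$area_label)
  if (!is.null(x$period)) cat(" over", format(x$period))
  cat("\n")
  invisible(x)
}
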