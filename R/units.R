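# Mass units accepted in configurations. The canonical internal mass unit is
# the gram; durable goods are counted in discrete units ("units").

GRAMS_PER_KG <- 1e3
GRAMS_PER_MT <- 1e6

SUPPLY_UNITS <- c("grams", "kilograms", "metric_tons", "units")

unit_to_grams_factor <- function(unit) {
  switch(unit,
    grams = 1,
    kilograms = GRAMS_PER_KG,
    metric_tons = GRAMS_PER_MT,
    units = 1,
    abort_validation(sprintf(
      "unknown unit '%s' (expected one of %s)",
      unit, paste(SUPPLY_UNITS, collapse = ", ")
    ))
  )
}

#' Convert a quantity to canonical internal units
#'
#' Mass quantities are carried internally in grams (1 metric ton =
#' 1,000,000 g); durable-good quantities are carried as unit counts.
#'
#' @param quantity numeric quantity in `unit`.
#' @param unit one of `"grams"`, `"kilograms"`, `"metric_tons"`, `"units"`.
#' @return Quantity in grams (mass) or unit count (durables).
#' @examples
#' to_grams(11174.56, "metric_tons")
#' @export
to_grams <- function(quantity, unit) {
  quantity * unit_to_grams_factor(unit)
}
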