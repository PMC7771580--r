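#' Rounding policy for the reach pipeline
#'
#' The estimation pipeline can run in two arithmetic modes:
#'
#' * `"full_precision"` (default): all intermediates are carried at full
#'   floating-point precision and only final headcounts are rounded
#'   (half-up) to whole persons.
#' * `"replication"`: intermediates are additionally rounded to the
#'   precision at which a desk calculation would print them, so that chained
#'   results match a published worked example digit for digit. Concretely:
#'   the effective daily amount is rounded to 0.1 g, the per-consumer period
#'   mass to 1 g, per-segment supply to 0.01 metric tons, and headcounts
#'   half-up to whole persons.
#'
#' Half-up rounding is used throughout for headcounts (and for replication
#' intermediates) because published worked examples round 0.5 away from
#' zero; base R's [round()] rounds half to even and cannot reproduce them.
#'
#' @param mode `"full_precision"` or `"replication"`.
#' @return An object of class `rounding_policy`.
#' @examples
#' rounding_policy("replication")
#' @export
rounding_policy <- function(mode = c("full_precision", "replication")) {
  mode <- match.arg(mode)
  structure(list(mode = mode), class = "rounding_policy")
}

as_rounding_policy <- function(policy) {
  if (inherits(policy, "rounding_policy")) return(policy)
  if (is.character(policy) && length(policy) == 1L) return(rounding_policy(policy))
  abort_validation("`policy` must be a rounding_policy or a mode string")
}

#' @export
print.rounding_policy <- function(x, ...) {
  cat("<rounding_policy>", x$mode, "\n")
  invisible(x)
}

#' Round half away from zero
#'
#' Deterministic half-up rounding (0.5 rounds away from zero), as used for
#' headcounts and for replication-mode intermediates.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.345), c(0, 0, 2))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Headcounts are rounded half-up to whole persons under both policies.
round_headcount <- function(x, policy) {
  round_half_up(x, 0)
}

# Replication-mode intermediate rounding; identity under full precision.
round_daily_grams <- function(x, policy) {
  if (policy$mode == "replication") round_half_up(x, 1) else x
}

round_period_grams <- function(x, policy) {
  if (policy$mode == "replication") round_half_up(x, 0) else x
}

round_segment_supply_grams <- function(x, policy) {
  if (policy$mode == "replication") {
    round_half_up(x / GRAMS_PER_MT, 2) * GRAMS_PER_MT
  } else {
    x
  }
}
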