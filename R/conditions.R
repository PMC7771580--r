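# Condition classes used across the package.
#
# Validation failures (bad configuration, out-of-range fields, malformed
# ledgers) signal "reach_validation_error"; arithmetic/consistency failures
# (inconsistent flows, zero denominators, the monthly-sum guard) signal
# "reach_arithmetic_error". The CLI maps these to exit codes 2 and 3.

abort_validation <- function(msg) {
  stop(structure(
    class = c("reach_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_arithmetic <- function(msg, subclass = character()) {
  stop(structure(
    class = c(subclass, "reach_arithmetic_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Collects multiple validation failures so a config is reported in one pass.
fail_collector <- function() {
  msgs <- character()
  list(
    add = function(msg) msgs <<- c(msgs, msg),
    ok = function() length(msgs) == 0L,
    raise = function(context) {
      if (length(msgs) > 0L) {
        abort_validation(paste0(
          context, ":\n", paste0("  - ", msgs, collapse = "\n")
        ))
      }
      invisible(TRUE)
    }
  )
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_proportion <- function(x) {
  is_scalar_number(x) && x >= 0 && x <= 1
}
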