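#' Define an estimation period of whole calendar months
#'
#' The reach model estimates over a defined period. Periods are restricted
#' to whole calendar months: the period runs from the first day of
#' `start` through the last day of `end`, inclusive. Partial months are not
#' supported because supply data (sales, dispatch) is typically reported
#' monthly and the worked examples this package reproduces use whole-month
#' windows.
#'
#' @param start,end year-months, as `"YYYY-MM"` strings (or `Date`s, whose
#'   day-of-month is ignored).
#' @param label optional free-text label.
#' @return An object of class `reach_period` with fields `start` and `end`
#'   (first-of-month `Date`s) and `label`.
#' @examples
#' p <- reach_period("2013-02", "2015-04")
#' period_length_days(p)
#' @export
reach_period <- function(start, end, label = NULL) {
  start <- parse_year_month(start, "start")
  end <- parse_year_month(end, "end")
  if (start > end) {
    abort_validation(sprintf(
      "invalid period: end month (%s) precedes start month (%s)",
      format(end, "%Y-%m"), format(start, "%Y-%m")
    ))
  }
  p <- structure(
    list(start = start, end = end,
         label = if (is.null(label)) sprintf("%s to %s", format(start, "%Y-%m"),
                                             format(end, "%Y-%m")) else label),
    class = "reach_period"
  )
  stopifnot(period_length_days(p) >= 28L)
  p
}

parse_year_month <- function(x, what) {
  if (inherits(x, "Date")) {
    return(as.Date(format(x, "%Y-%m-01")))
  }
  if (!is.character(x) || length(x) != 1L || !grepl("^\\d{4}-\\d{2}$", x)) {
    abort_validation(sprintf(
      "period %s must be a 'YYYY-MM' string, got %s", what, deparse(x)
    ))
  }
  d <- as.Date(paste0(x, "-01"))
  if (is.na(d)) abort_validation(sprintf("unparseable period %s: '%s'", what, x))
  d
}

# First day of the month after `d` (a first-of-month Date).
next_month <- function(d) {
  seq(d, by = "1 month", length.out = 2L)[2L]
}

last_day_of_month <- function(d) {
  next_month(as.Date(format(d, "%Y-%m-01"))) - 1L
}

#' Inclusive day count of an estimation period
#'
#' Counts calendar days from the first day of the start month through the
#' last day of the end month, inclusive, honouring leap years. A 27-month
#' window from February 2013 through April 2015 spans 819 days.
#'
#' @param period a [reach_period()].
#' @return Integer day count.
#' @examples
#' period_length_days(reach_period("2013-02", "2015-04")) # 819
#' period_length_days(reach_period("2016-02", "2016-02")) # 29, leap year
#' @export
period_length_days <- function(period) {
  stopifnot(inherits(period, "reach_period"))
  as.integer(last_day_of_month(period$end) - period$start) + 1L
}

#' Number of months in an estimation period
#'
#' @param period a [reach_period()].
#' @return Integer month count (inclusive of both end months).
#' @export
period_length_months <- function(period) {
  12L * (as.integer(format(period$end, "%Y")) - as.integer(format(period$start, "%Y"))) +
    (as.integer(format(period$end, "%m")) - as.integer(format(period$start, "%m"))) + 1L
}

#' Average number of days in a calendar month
#'
#' Returns the one-decimal convention 365/12 = 30.4 days used when a use
#' duration is quoted as "one month" without reference to specific calendar
#' months (for example, trial consumers who use a product for about a
#' month). Note this convention is deliberately not reconciled with the
#' exact day count of any particular period: a 27-month window of 819 days
#' averages 30.33 days/month, but quoted one-month durations conventionally
#' use 30.4.
#'
#' @return 30.4
#' @examples
#' average_month_days()
#' @export
average_month_days <- function() {
  round_half_up(365 / 12, 1)
}

#' @export
print.reach_period <- function(x, ...) {
  cat(sprintf("<reach_period> %s (%d months, %d days)\n",
              x$label, period_length_months(x), period_length_days(x)))
  invisible(x)
}

#' @export
format.reach_period <- function(x, ...) {
  sprintf("%s..%s", format(x$start, "%Y-%m"), format(x$end, "%Y-%m"))
}

# Sequence of first-of-month Dates covering the period.
period_months <- function(period) {
  seq(period$start, period$end, by = "1 month")
}
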