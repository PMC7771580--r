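#' Ingest a dated supply-ledger CSV
#'
#' Point-of-sale or dispatch data often arrives as dated records. The
#' ledger CSV must have columns `date` (ISO-8601, `YYYY-MM-DD`), `region`,
#' `quantity`, and `unit` (grams/kilograms/metric_tons/units). Rows dated
#' inside the period are summed (in grams) into a sales volume; rows outside
#' the period are excluded and counted, with a message reporting the count.
#' Malformed rows (unparseable date, unknown unit, non-numeric quantity)
#' are reported together as a row-level error.
#'
#' @param path path to the CSV file.
#' @param period a [reach_period()] delimiting in-period rows.
#' @return A list with `total_grams` (sum of in-period quantities),
#'   `excluded_count`, `excluded_rows` (the out-of-period rows), and
#'   `by_month` (data frame of per-month gram totals, for
#'   [monthly_reach()]).
#' @export
load_supply_ledger <- function(path, period) {
  stopifnot(inherits(period, "reach_period"))
  if (!file.exists(path)) {
    abort_validation(sprintf("supply ledger not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("date", "region", "quantity", "unit")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_validation(sprintf("supply ledger lacks column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    return(list(total_grams = 0, excluded_count = 0L,
                excluded_rows = df,
                by_month = data.frame(month = character(), grams = numeric())))
  }
  fc <- fail_collector()
  dates <- as.Date(rep(NA_integer_, nrow(df)))
  ok_iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", df$date)
  dates[ok_iso] <- as.Date(df$date[ok_iso])
  grams <- rep(NA_real_, nrow(df))
  qty <- suppressWarnings(as.numeric(df$quantity))
  for (i in seq_len(nrow(df))) {
    if (!ok_iso[i] || is.na(dates[i])) {
      fc$add(sprintf("row %d: unparseable ISO-8601 date '%s'", i, df$date[i]))
      next
    }
    if (is.na(qty[i]) || qty[i] < 0) {
      fc$add(sprintf("row %d: invalid quantity '%s'", i, df$quantity[i]))
      next
    }
    if (!df$unit[i] %in% SUPPLY_UNITS) {
      fc$add(sprintf("row %d: unknown unit '%s'", i, df$unit[i]))
      next
    }
    grams[i] <- to_grams(qty[i], df$unit[i])
  }
  fc$raise(sprintf("supply ledger '%s' has invalid rows", path))

  start <- period$start
  end <- last_day_of_month(period$end)
  in_period <- dates >= start & dates <= end
  excluded <- sum(!in_period)
  if (excluded > 0) {
    message(sprintf(
      "supply ledger: excluded %d row(s) outside %s", excluded, format(period)
    ))
  }
  if (any(in_period)) {
    months <- format(dates[in_period], "%Y-%m")
    by_month <- stats::aggregate(
      list(grams = grams[in_period]), by = list(month = months), FUN = sum
    )
    by_month <- by_month[order(by_month$month), , drop = FALSE]
    rownames(by_month) <- NULL
  } else {
    by_month <- data.frame(month = character(), grams = numeric())
  }
  list(total_grams = sum(grams[in_period]),
       excluded_count = as.integer(excluded),
       excluded_rows = df[!in_period, , drop = FALSE],
       by_month = by_month)
}
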