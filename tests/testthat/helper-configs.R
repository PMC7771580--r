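# Fixtures built in code: minimal valid configurations for each product
# type, and a writer to exercise the file-loading path.

fm_config <- function(sales_mt = 100, base_daily = 40, use_days = "period",
                      quality = 1, losses = 1, leakage = 0,
                      start = "2020-01", end = "2020-12", ...) {
  c(list(
    product_name = "test fast-moving product",
    product_type = "fast_moving",
    period = list(start = start, end = end),
    supply = list(mode = "sales_distribution", sales_volume = sales_mt,
                  unit = "metric_tons", quality_factor = quality,
                  losses_factor = losses, leakage_fraction = leakage),
    use = list(type = "fast_moving", base_daily_amount = base_daily,
               use_days = use_days)
  ), list(...))
}

durable_config <- function(units = 1000, users = 1, length_days = 365,
                           start = "2020-01", end = "2024-12", ...) {
  c(list(
    product_name = "test durable product",
    product_type = "durable",
    period = list(start = start, end = end),
    supply = list(mode = "sales_distribution", sales_volume = units,
                  unit = "units"),
    use = list(type = "durable", users_per_unit = users,
               length_of_use_days = length_days)
  ), list(...))
}

write_tmp_yaml <- function(cfg) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  path
}

brazil_config <- function() load_config(brazil_fixture_path())

write_tmp_ledger <- function(rows) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}
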