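#' Generate a random valid product configuration with known reach
#'
#' Deterministically (per seed) draws a product configuration from
#' documented ranges — supply 10 to 5,000 metric tons (100 to 100,000 units
#' for durables), adjustment factors in \[0.7, 1\], leakage up to 20%, base
#' daily amounts 5-300 g with up to three multipliers in \[0.3, 1\], periods
#' of 1-36 whole months between 2005 and 2020, optional repeat/trial
#' segmentation — and returns it together with the analytically-known
#' full-precision reach, computed here by direct closed-form arithmetic.
#' The bundled truth serves as an independent oracle for the estimation
#' engine in property tests.
#'
#' The global RNG state is left untouched.
#'
#' @param seed integer seed; the same seed always yields the same config.
#' @param product_type `"fast_moving"`, `"durable"`, or `"razor_blade"`.
#' @return A list with `config` (a plain configuration list accepted by
#'   [validate_config()]) and `truth` (list with `total_reach` and, when
#'   segmented, `segment_reach`).
#' @examples
#' g <- generate_synthetic_config(1, "fast_moving")
#' estimate_reach(g$config)$total_reach == g$truth$total_reach
#' @export
generate_synthetic_config <- function(seed,
                                      product_type = c("fast_moving",
                                                       "durable",
                                                       "razor_blade")) {
  product_type <- match.arg(product_type)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  # period of whole months; day count computed inline from the calendar
  n_months <- sample(1:36, 1)
  start <- as.Date(sprintf("%d-%02d-01", sample(2005:2020, 1), sample(1:12, 1)))
  end <- seq(start, by = "1 month", length.out = n_months)[n_months]
  end_next <- seq(end, by = "1 month", length.out = 2)[2]
  days <- as.integer(end_next - start)
  period <- list(start = format(start, "%Y-%m"), end = format(end, "%Y-%m"))

  draw_factors <- function() {
    list(quality = round(stats::runif(1, 0.7, 1), 3),
         losses = round(stats::runif(1, 0.8, 1), 3),
         leakage = round(stats::runif(1, 0, 0.2), 3))
  }

  make_fast_moving <- function() {
    f <- draw_factors()
    sales_mt <- round(stats::runif(1, 10, 5000), 2)
    k <- sample(0:3, 1)
    mult <- round(stats::runif(k, 0.3, 1), 3)
    names(mult) <- if (k > 0) paste0("adjustment_", seq_len(k)) else NULL
    divisor <- sample(c(1, 2, 2.5), 1)
    base <- round(stats::runif(1, 5, 300), 1)
    use_days <- if (stats::runif(1) < 0.5) "period"
                else sample(seq_len(days), 1)
    segmented <- stats::runif(1) < 0.5
    cfg <- list(
      product_name = sprintf("synthetic fast-moving #%d", seed),
      product_type = "fast_moving",
      period = period,
      supply = list(mode = "sales_distribution", sales_volume = sales_mt,
                    unit = "metric_tons", quality_factor = f$quality,
                    losses_factor = f$losses, leakage_fraction = f$leakage),
      use = list(type = "fast_moving", base_daily_amount = base,
                 amount_basis = "measured",
                 multipliers = if (k > 0) lapply(seq_len(k), function(i)
                   list(name = names(mult)[i], value = mult[[i]])) else NULL,
                 conversion_divisor = divisor, use_days = use_days,
                 frequency_basis = "measured")
    )
    supply_g <- sales_mt * 1e6 * (1 - f$leakage) * f$quality * f$losses
    daily_g <- base * prod(mult) / divisor
    days1 <- if (identical(use_days, "period")) days else use_days
    if (segmented) {
      share <- round(stats::runif(1, 0.55, 0.95), 2)
      days2 <- sample(seq_len(days), 1)
      cfg$segments <- list(
        list(name = "repeat", supply_share = share, use_days = use_days),
        list(name = "trial", supply_share = round(1 - share, 2),
             use_days = days2)
      )
      r1 <- floor(share * supply_g / (daily_g * days1) + 0.5)
      r2 <- floor((1 - share) * supply_g / (daily_g * days2) + 0.5)
      truth <- list(total_reach = r1 + r2,
                    segment_reach = c(repeat_ = r1, trial = r2))
    } else {
      truth <- list(total_reach = floor(supply_g / (daily_g * days1) + 0.5))
    }
    list(config = cfg, truth = truth)
  }

  make_durable <- function() {
    f <- draw_factors()
    n_units <- sample(100:100000, 1)
    scalar_d <- stats::runif(1) < 0.5
    if (scalar_d) {
      d <- sample(1:8, 1)
      use <- list(type = "durable", users_per_unit = d,
                  basis = "measured")
    } else {
      w <- stats::runif(sample(2:3, 1))
      w <- w / sum(w)
      u <- sample(1:10, length(w))
      d <- sum(w * u)
      use <- list(type = "durable",
                  household_distribution = lapply(seq_along(w), function(i)
                    list(weight = w[i], users = u[i])),
                  basis = "measured")
    }
    lou <- round(stats::runif(1, 30, days * 2), 1)
    use$length_of_use_days <- lou
    cfg <- list(
      product_name = sprintf("synthetic durable #%d", seed),
      product_type = "durable",
      period = period,
      supply = list(mode = "sales_distribution", sales_volume = n_units,
                    unit = "units", quality_factor = f$quality,
                    losses_factor = f$losses, leakage_fraction = f$leakage),
      use = use
    )
    units_eff <- n_units * (1 - f$leakage) * f$quality * f$losses
    turn <- if (lou >= days) 1 else days / lou
    list(config = cfg,
         truth = list(total_reach = floor(units_eff * d / turn + 0.5)))
  }

  if (product_type == "fast_moving") return(make_fast_moving())
  if (product_type == "durable") return(make_durable())

  # razor-and-blade: durable razor and/or fast-moving blade components
  which_comp <- sample(c("both", "razor", "blade"), 1,
                       prob = c(0.6, 0.2, 0.2))
  razor <- if (which_comp != "blade") make_durable()
  blade <- if (which_comp != "razor") make_fast_moving()
  comps <- list()
  truths <- numeric()
  if (!is.null(razor)) {
    comps$razor <- list(supply = razor$config$supply, use = razor$config$use)
    truths["razor"] <- razor$truth$total_reach
  }
  if (!is.null(blade)) {
    bl <- blade$config
    bl$segments <- NULL  # components carry a single use pattern
    comps$blade <- list(supply = bl$supply, use = bl$use)
    daily_g <- bl$use$base_daily_amount *
      prod(vapply(bl$use$multipliers, function(m) m$value, numeric(1))) /
      bl$use$conversion_divisor
    days_b <- if (identical(bl$use$use_days, "period")) days else bl$use$use_days
    supply_g <- bl$supply$sales_volume * 1e6 *
      (1 - bl$supply$leakage_fraction) *
      bl$supply$quality_factor * bl$supply$losses_factor
    truths["blade"] <- floor(supply_g / (daily_g * days_b) + 0.5)
  }
  cfg <- list(
    product_name = sprintf("synthetic razor-blade #%d", seed),
    product_type = "razor_blade",
    period = period,
    components = comps
  )
  list(config = cfg,
       truth = list(total_reach = min(truths), component_reach = truths))
}
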