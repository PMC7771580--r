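#' Packaged fortified-rice case study (Brazil)
#'
#' The package ships a fully worked fixture: a voluntary fortified-rice
#' introduction in Brazil, February 2013 through April 2015 (27 months, 819
#' days), with 11,174.56 metric tons of fortified rice dispatched to
#' retailers, quality and losses adjustment factors of 1, a measured cooked
#' per-capita consumption of 160.3 g/day adjusted by the share of rice
#' consumed at home (85%) and the fortified share of home rice consumption
#' (60%), converted to dry mass by dividing by 2.5; repeat consumers (82% of
#' buyers, consuming over the whole period) and trial consumers (18%,
#' consuming for about one month, 30.4 days); and three population
#' subgroups (women 15-49: 28.14%; children 6 months-5 years: 6.54%; lower
#' socio-economic classes: 74.1%).
#'
#' `brazil_fixture_path()` returns the path of the packaged YAML config (or
#' of the companion supply-ledger CSV). The monthly ledger is *synthetic*:
#' the case reports only the 27-month total, so the CSV spreads it
#' near-uniformly (26 months of 413.87 MT plus one remainder month of
#' 413.94 MT, summing exactly to 11,174.56 MT).
#'
#' `write_brazil_fixture()` copies both files into a directory, e.g. as a
#' starting point for a new configuration.
#'
#' @param which `"config"` or `"ledger"`.
#' @return `brazil_fixture_path()`: a file path. `write_brazil_fixture()`:
#'   the directory, invisibly.
#' @examples
#' estimate_reach(load_config(brazil_fixture_path()), "replication")
#' @export
brazil_fixture_path <- function(which = c("config", "ledger")) {
  which <- match.arg(which)
  fn <- switch(which,
               config = "brazil_fortified_rice.yaml",
               ledger = "brazil_supply_ledger_synthetic.csv")
  system.file("extdata", fn, package = "reachcalc", mustWork = TRUE)
}

#' @rdname brazil_fixture_path
#' @param dir destination directory (created if missing).
#' @export
write_brazil_fixture <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (w in c("config", "ledger")) {
    file.copy(brazil_fixture_path(w), dir, overwrite = TRUE)
  }
  invisible(dir)
}
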