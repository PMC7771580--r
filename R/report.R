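# Report serialization. Output is bit-stable for a fixed bundle: keys are
# sorted, numbers are written at fixed precision (headcounts as integers,
# metric tons to 2 decimals, grams to 1 decimal), and no timestamps are
# embedded.

sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, sort_keys)
  } else if (is.list(x)) {
    lapply(x, sort_keys)
  } else {
    x
  }
}

bundle_to_list <- function(bundle) {
  reach <- bundle$reach
  out <- list(
    product_name = bundle$product_name,
    formula = reach$formula_used,
    policy = reach$policy$mode,
    total_reach = as.integer(round(reach$total_reach)),
    provenance = bundle$provenance,
    assumptions = lapply(seq_len(nrow(reach$assumptions_ledger)), function(i)
      as.list(reach$assumptions_ledger[i, , drop = FALSE]))
  )
  if (!is.null(reach$segment_reach)) {
    out$segments <- as.list(vapply(reach$segment_reach,
                                   function(v) as.integer(round(v)), integer(1)))
  }
  if (!is.null(reach$subgroup_reach)) {
    out$subgroups <- as.list(vapply(reach$subgroup_reach,
                                    function(v) as.integer(round(v)), integer(1)))
  }
  d <- reach$details
  if (!is.null(d$effective_supply_g)) {
    out$effective_supply_mt <- round(d$effective_supply_g / GRAMS_PER_MT, 2)
  }
  if (!is.null(d$per_consumer_use_g)) {
    out$per_consumer_use_g <- round(d$per_consumer_use_g, 1)
  }
  if (!is.null(d$segment_supply_g)) {
    out$segment_supply_mt <- as.list(round(d$segment_supply_g / GRAMS_PER_MT, 2))
    out$segment_use_g <- as.list(round(d$segment_use_g, 1))
  }
  if (!is.null(bundle$scenario_range)) {
    sr <- bundle$scenario_range
    out$scenario_range <- list(
      low_reach = as.integer(round(sr$low_reach)),
      high_reach = as.integer(round(sr$high_reach)),
      low_scenario = sr$low_scenario,
      high_scenario = sr$high_scenario,
      per_scenario = as.list(vapply(sr$per_scenario, function(r)
        as.integer(round(r$total_reach)), integer(1)))
    )
  }
  if (!is.null(bundle$triangulation)) {
    tr <- bundle$triangulation
    out$triangulation <- list(
      coverage_based_reach = as.integer(round(tr$coverage_based_reach)),
      supply_based_reach = as.integer(round(tr$supply_based_reach)),
      ratio_supply_to_coverage = round(tr$ratio_supply_to_coverage, 4)
    )
  }
  sort_keys(out)
}

bundle_to_table <- function(bundle) {
  reach <- bundle$reach
  rows <- data.frame(scope = "total", name = bundle$product_name,
                     reach = as.integer(round(reach$total_reach)),
                     stringsAsFactors = FALSE)
  if (!is.null(reach$segment_reach)) {
    rows <- rbind(rows, data.frame(
      scope = "segment", name = names(reach$segment_reach),
      reach = as.integer(round(unname(reach$segment_reach)))))
  }
  if (!is.null(reach$subgroup_reach)) {
    rows <- rbind(rows, data.frame(
      scope = "subgroup", name = names(reach$subgroup_reach),
      reach = as.integer(round(unname(reach$subgroup_reach)))))
  }
  rows
}

#' Write a reach report to disk
#'
#' Serializes a [report_bundle()] (or a bare [reach_result], which is
#' wrapped) as JSON (sorted keys, fixed numeric precision) or as a flat CSV
#' with one row per total/segment/subgroup. Writing the same bundle twice
#' produces byte-identical files.
#'
#' @param bundle a `report_bundle` or `reach_result`.
#' @param path output file path.
#' @param format `"json"` or `"csv"`; defaults to the file extension.
#' @return The path, invisibly.
#' @export
write_report <- function(bundle, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (inherits(bundle, "reach_result")) {
    bundle <- structure(list(reach = bundle, scenario_range = NULL,
                             triangulation = NULL,
                             provenance = list(
                               config_hash = NA_character_,
                               policy = bundle$policy$mode,
                               tool_version =
                                 as.character(utils::packageVersion("reachcalc"))),
                             product_name = "reach estimate"),
                        class = "report_bundle")
  }
  stopifnot(inherits(bundle, "report_bundle"))
  if (format == "json") {
    json <- jsonlite::toJSON(bundle_to_list(bundle), auto_unbox = TRUE,
                             digits = NA, null = "null", na = "null",
                             pretty = TRUE)
    writeLines(json, path)
  } else {
    utils::write.csv(bundle_to_table(bundle), path, row.names = FALSE,
                     quote = TRUE)
  }
  invisible(path)
}

#' Re-read a written JSON report
#'
#' Convenience inverse of [write_report()] for round-trip checks and
#' downstream tooling.
#'
#' @param path path to a JSON report written by [write_report()].
#' @return The report as a list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
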