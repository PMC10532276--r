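#' Tabulate scenario results
#'
#' One row per solved structure; one column per terminal product of the
#' network. A product's rate is reported only when the product material is
#' part of the structure — otherwise the cell reads `"N.A."` (the outcome is
#' structurally absent, not zero). The null structure therefore reports
#' `"N.A."` in every product column.
#'
#' @param results List of scenario results: each element needs `structure`
#'   (a [solution_structure()]), `flow` (a `"flow_result"`) and optionally
#'   `label` and `scenario` (a `"scenario_config"` or description string).
#' @param network The [process_network()] whose products define the columns.
#' @param digits Decimal places for the reported rates; values are printed
#'   at this precision (default 3, the usual table convention; use more for
#'   pass-through).
#' @return A data frame with columns `SolutionStructure`,
#'   `RepresentedScenario`, one column per product, and `Units` (the
#'   structure's unit set).
#' @export
scenario_report <- function(results, network, digits = 3) {
  stopifnot(length(results) > 0)
  prods <- network$products
  rows <- lapply(results, function(res) {
    s <- res$structure
    fl <- res$flow
    lab <- res$label %||% s$label %||% ""
    desc <- if (inherits(res$scenario, "scenario_config")) res$scenario$description
            else res$scenario %||% ""
    vals <- vapply(prods, function(p) {
      if (!(p %in% s$material_ids)) return("N.A.")
      format(round(fl$net_flows[[p]], digits), trim = TRUE,
             scientific = FALSE, drop0trailing = TRUE)
    }, character(1))
    c(SolutionStructure = lab, RepresentedScenario = desc,
      stats::setNames(vals, prods),
      Units = paste(s$unit_ids, collapse = "; "))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Extract a product rate from a scenario result
#'
#' @param result One element of a [run_all_scenarios()] `results` list.
#' @param product Product material id.
#' @return The net flow, or `NA` if the product is absent from the structure.
#' @export
product_rate <- function(result, product) {
  if (!(product %in% result$structure$material_ids)) return(NA_real_)
  unname(result$flow$net_flows[[product]])
}

#' Write a scenario report as CSV
#'
#' Comma-separated, UTF-8, header row; deterministic output (no timestamps),
#' so identical runs produce byte-identical files.
#'
#' @param table A [scenario_report()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize structures and flows as JSON
#'
#' Machine-readable companion to the CSV report. The run configuration is
#' echoed into the document for provenance; output is deterministic for
#' identical inputs.
#'
#' @param results As for [scenario_report()].
#' @param path Output path.
#' @param config Optional named list echoed under `$config`.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path, config = NULL) {
  doc <- list(
    config = config,
    results = lapply(unname(results), function(res) {
      list(label = res$label %||% res$structure$label,
           scenario = if (inherits(res$scenario, "scenario_config"))
             res$scenario$name else res$scenario,
           units = as.list(res$structure$unit_ids),
           materials = as.list(res$structure$material_ids),
           status = res$flow$status,
           objective_value = res$flow$objective_value,
           levels = as.list(res$flow$levels),
           net_flows = as.list(res$flow$net_flows))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
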