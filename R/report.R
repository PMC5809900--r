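#' Render a results table with the published rounding rules
#'
#' Effectiveness and incremental effectiveness are reported to one decimal
#' place (percent); costs and radiation doses are rounded to integers.
#' Rounding happens only here, at the reporting layer; the underlying
#' `vf_results` object keeps full precision.
#'
#' @param results A `vf_results` data frame from [run_base_case()] /
#'   [run_scenario()].
#' @return A data frame of formatted character columns, also printed by
#'   `print.vf_results`.
#' @export
render_results_table <- function(results) {
  stopifnot(inherits(results, "vf_results"))
  fmt1 <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))
  fmt0 <- function(x) ifelse(is.na(x), "", sprintf("%.0f", x))
  data.frame(
    sex = results$sex,
    strategy = results$strategy,
    effectiveness_pct = fmt1(results$effectiveness),
    delta_e = fmt1(results$delta_e),
    cost_eur = fmt0(results$cost),
    delta_c = fmt0(results$delta_c),
    delta_re = fmt0(results$delta_re),
    row.names = NULL
  )
}

#' @export
print.vf_results <- function(x, ...) {
  cat(sprintf("<vf_results> scenario %s\n", attr(x, "scenario")))
  print(render_results_table(x), right = TRUE)
  invisible(x)
}

#' Write a results table (full precision) and its rounded display to CSV
#'
#' @param results A `vf_results` data frame.
#' @param path Output CSV path (full precision); a second file with suffix
#'   `_display` receives the rounded table.
#' @return Invisibly, the paths written.
#' @export
write_results_csv <- function(results, path) {
  stopifnot(inherits(results, "vf_results"))
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  disp <- sub("(\\.csv)?$", "_display.csv", path)
  disp <- sub("_display\\.csv_display\\.csv$", "_display.csv", disp)
  utils::write.csv(render_results_table(results), disp, row.names = FALSE)
  invisible(c(path, disp))
}

#' Write a run manifest capturing the exact configuration of an output
#'
#' Every emitted result file should be paired with a manifest recording the
#' package version, scenario, active convention switches, seed (if any) and
#' output files, so any run is reproducible from its manifest alone.
#'
#' @param path Manifest path (YAML).
#' @param scenario Scenario label.
#' @param conventions A [vf_conventions] object.
#' @param outputs Character vector of files this manifest covers.
#' @param seed Integer seed for stochastic runs, or `NULL`.
#' @return Invisibly, `path`.
#' @export
write_run_manifest <- function(path, scenario, conventions, outputs,
                               seed = NULL) {
  man <- list(
    tool = "vfscreen",
    version = as.character(utils::packageVersion("vfscreen")),
    scenario = scenario,
    conventions = unclass(conventions),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.character(outputs)
  )
  yaml::write_yaml(man, path)
  invisible(path)
}
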