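#' Export results as a tidy long-format table
#'
#' One row per (plot, date, variable, value) — the shape a dashboard or
#' database loader consumes. Balance trajectories contribute `smd_mm`,
#' `aet_mm` and `drainage_mm`; the optional canopy series contributes
#' `cover`. Values round-trip losslessly through [read_long_table()].
#'
#' @param trajectories A nonempty balance trajectory tibble (all plots).
#' @param canopy_daily Optional daily cover tibble; `NULL` omits cover rows.
#' @param path Output CSV path.
#' @return The number of rows written, invisibly.
#' @export
export_long_table <- function(trajectories, canopy_daily = NULL, path) {
  if (is.null(trajectories) || !nrow(trajectories)) {
    wb_abort("invariant", "trajectories must be nonempty")
  }
  long <- tidyr::pivot_longer(
    trajectories[c("plot_id", "date", "smd_mm", "aet_mm", "drainage_mm")],
    cols = c("smd_mm", "aet_mm", "drainage_mm"),
    names_to = "variable", values_to = "value")
  if (!is.null(canopy_daily) && nrow(canopy_daily)) {
    long <- bind_rows(long, tibble(plot_id = canopy_daily$plot_id,
                                   date = canopy_daily$date,
                                   variable = "cover",
                                   value = canopy_daily$cover))
  }
  long <- arrange(long, .data$plot_id, .data$date, .data$variable)
  ok <- tryCatch({
    readr::write_csv(long, path, progress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    wb_abort("io", sprintf("failed to write '%s': %s", path,
                           conditionMessage(ok)))
  }
  invisible(nrow(long))
}

#' Read a long-format results table back
#'
#' @param path CSV written by [export_long_table()].
#' @return A tibble `plot_id`, `date`, `variable`, `value`.
#' @export
read_long_table <- function(path) {
  out <- read_contract_csv(path, list(plot_id = "character", date = "date",
                                      variable = "character",
                                      value = "double"), "long results")
  require_no_na(out, "long results")
  out
}
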