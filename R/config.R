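#' Trial configuration
#'
#' Global parameters shared by every stage of the pipeline: the accounting
#' depth of the soil profile, the NDVI-to-cover mapping endpoints, the
#' recurring winter fallow window used for field-capacity estimation, the
#' drainage-event segmentation thresholds, and the optional soil-dryness
#' stress model of the water balance.
#'
#' @param profile_depth_cm Depth (cm) of the soil profile over which water is
#'   accounted. Default 60.
#' @param ndvi_closure NDVI value at which canopy closure (cover fraction 1)
#'   is reached, applied to all crops. Default 0.75.
#' @param ndvi_bare NDVI of bare soil, mapped to cover fraction 0.
#'   Default 0.15.
#' @param fallow_months Integer months (1--12) of the recurring winter fallow
#'   window. Default June--August (`6:8`), the low-evaporation season in the
#'   southern hemisphere.
#' @param fc_rule How field capacity is taken from winter-fallow storages:
#'   `"max"` (the wettest reading) or `"quantile"`.
#' @param fc_quantile Empirical quantile used when `fc_rule = "quantile"`,
#'   in (0, 1]. Default 0.95.
#' @param event_min_mm Minimum total drainage (mm) for a run of draining days
#'   to count as an event. Default 1.
#' @param event_merge_gap_days Runs of draining days separated by at most this
#'   many dry days are merged into one event. Default 1.
#' @param stress_model `"off"` (actual ET limited by canopy cover only) or
#'   `"linear"` (additionally reduced linearly between readily and total
#'   available water).
#' @param taw_mm,raw_mm Total and readily available water (mm), required when
#'   `stress_model = "linear"`; `raw_mm < taw_mm`. When `stress_model = "off"`
#'   a supplied `taw_mm` is only used to warn when the modelled deficit
#'   exceeds it.
#' @param seed Integer seed recorded alongside the configuration for
#'   reproducible synthetic runs.
#'
#' @return An object of class `trial_config` (a validated named list).
#' @examples
#' cfg <- trial_config()
#' cover_fraction(0.75, cfg) # canopy closure
#' @export
trial_config <- function(profile_depth_cm = 60,
                         ndvi_closure = 0.75,
                         ndvi_bare = 0.15,
                         fallow_months = 6:8,
                         fc_rule = c("max", "quantile"),
                         fc_quantile = 0.95,
                         event_min_mm = 1,
                         event_merge_gap_days = 1,
                         stress_model = c("off", "linear"),
                         taw_mm = NULL,
                         raw_mm = NULL,
                         seed = 1L) {
  fc_rule <- match.arg(fc_rule)
  stress_model <- match.arg(stress_model)

  if (!is.numeric(profile_depth_cm) || length(profile_depth_cm) != 1 ||
      profile_depth_cm <= 0) {
    wb_abort("config", "profile_depth_cm must be a single positive number")
  }
  if (!(ndvi_bare >= 0 && ndvi_bare < ndvi_closure && ndvi_closure <= 1)) {
    wb_abort("config",
             "need 0 <= ndvi_bare < ndvi_closure <= 1 for the cover mapping")
  }
  fallow_months <- as.integer(fallow_months)
  if (!length(fallow_months) || anyNA(fallow_months) ||
      any(fallow_months < 1L | fallow_months > 12L)) {
    wb_abort("config", "fallow_months must be months in 1..12")
  }
  if (any(diff(sort(fallow_months)) != 1L)) {
    wb_abort("config", "fallow_months must be a contiguous block of months")
  }
  if (!is.numeric(fc_quantile) || fc_quantile <= 0 || fc_quantile > 1) {
    wb_abort("config", "fc_quantile must be in (0, 1]")
  }
  if (event_min_mm < 0) wb_abort("config", "event_min_mm must be >= 0")
  if (event_merge_gap_days < 0 ||
      event_merge_gap_days != as.integer(event_merge_gap_days)) {
    wb_abort("config", "event_merge_gap_days must be a nonnegative integer")
  }
  if (stress_model == "linear") {
    if (is.null(taw_mm) || is.null(raw_mm)) {
      wb_abort("config",
               "taw_mm and raw_mm are required when stress_model = 'linear'")
    }
    if (!(raw_mm >= 0 && raw_mm < taw_mm)) {
      wb_abort("config", "need 0 <= raw_mm < taw_mm")
    }
  }
  structure(
    list(profile_depth_cm = as.numeric(profile_depth_cm),
         ndvi_closure = as.numeric(ndvi_closure),
         ndvi_bare = as.numeric(ndvi_bare),
         fallow_months = sort(fallow_months),
         fc_rule = fc_rule,
         fc_quantile = as.numeric(fc_quantile),
         event_min_mm = as.numeric(event_min_mm),
         event_merge_gap_days = as.integer(event_merge_gap_days),
         stress_model = stress_model,
         taw_mm = if (!is.null(taw_mm)) as.numeric(taw_mm),
         raw_mm = if (!is.null(raw_mm)) as.numeric(raw_mm),
         seed = as.integer(seed)),
    class = "trial_config")
}

#' Read a trial configuration from a YAML file
#'
#' The file holds a flat mapping whose keys mirror the arguments of
#' [trial_config()] exactly; unknown keys are rejected rather than ignored so
#' that typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `trial_config` object.
#' @export
read_trial_config <- function(path) {
  if (!file.exists(path)) wb_abort("io", sprintf("config file not found: '%s'", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(trial_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    wb_abort("config", sprintf("unknown configuration key(s): %s",
                               paste(bad, collapse = ", ")))
  }
  do.call(trial_config, vals)
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config>\n")
  cat(sprintf("  profile depth: %g cm; NDVI bare/closure: %g / %g\n",
              x$profile_depth_cm, x$ndvi_bare, x$ndvi_closure))
  cat(sprintf("  fallow months: %s; FC rule: %s%s\n",
              paste(month.abb[x$fallow_months], collapse = "-"), x$fc_rule,
              if (x$fc_rule == "quantile") sprintf(" (q = %g)", x$fc_quantile) else ""))
  cat(sprintf("  events: min %g mm, merge gap %d d; stress model: %s\n",
              x$event_min_mm, x$event_merge_gap_days, x$stress_model))
  invisible(x)
}
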