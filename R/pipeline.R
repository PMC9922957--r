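#' Assemble daily forcings for one plot
#'
#' Joins weather with summed irrigation, the daily canopy cover series
#' (days without a cover value — outside the crop window — get cover 0) and
#' observed profile storages, over the weather date range.
#'
#' @param plot_id Plot identifier.
#' @param weather Weather tibble.
#' @param irrigation Irrigation records (all plots).
#' @param canopy_daily Daily cover series (all plots).
#' @param storages Profile storages (all plots), or `NULL`.
#' @return A forcings tibble suitable for [run_balance()].
#' @export
assemble_forcings <- function(plot_id, weather, irrigation, canopy_daily,
                              storages = NULL) {
  f <- tibble(plot_id = plot_id, date = weather$date,
              rain_mm = weather$rain_mm, pet_mm = weather$pet_mm)
  ir <- irrigation[irrigation$plot_id == plot_id, , drop = FALSE]
  if (nrow(ir)) {
    # several applications on one day are physically additive
    ir <- summarise(group_by(ir, date), amount_mm = sum(.data$amount_mm),
                    .groups = "drop")
    f$irrigation_mm <- ir$amount_mm[match(f$date, ir$date)]
    f$irrigation_mm[is.na(f$irrigation_mm)] <- 0
  } else {
    f$irrigation_mm <- 0
  }
  cd <- canopy_daily[canopy_daily$plot_id == plot_id, , drop = FALSE]
  f$cover <- cd$cover[match(f$date, cd$date)]
  f$cover[is.na(f$cover)] <- 0
  if (!is.null(storages)) {
    st <- storages[storages$plot_id == plot_id, , drop = FALSE]
    f$observed_storage_mm <- st$storage_mm[match(f$date, st$date)]
  } else {
    f$observed_storage_mm <- NA_real_
  }
  f
}

#' Run the full trial pipeline in memory
#'
#' NDVI standardisation and daily interpolation, probe aggregation,
#' field-capacity estimation, the corrected water balance per plot, and
#' drainage-event detection — the whole chain from a validated input bundle
#' to results.
#'
#' @param bundle A `trial_bundle` from [read_input_tables()] or
#'   [generate_trial()].
#' @param calibration Instrument calibration table for [standardise_ndvi()];
#'   defaults to the bundle's own `calibration` element if present, else
#'   identity.
#' @return A list with `canopy_daily`, `storages`, `fc`, `trajectories`
#'   (one trajectory tibble, all plots), and `events`.
#' @export
run_trial_pipeline <- function(bundle, calibration = NULL) {
  config <- bundle$config
  calibration <- calibration %||% bundle$calibration
  obs <- standardise_ndvi(bundle$canopy, calibration)
  canopy_daily <- interpolate_daily_cover(obs, bundle$calendar, config,
                                          fallow = bundle$fallow)
  storages <- profile_storage(bundle$probe, config)
  fc <- estimate_field_capacity(storages, config, fallow = bundle$fallow)
  trajectories <- bind_rows(lapply(bundle$calendar$plot_id, function(p) {
    f <- assemble_forcings(p, bundle$weather, bundle$irrigation,
                           canopy_daily, storages)
    run_balance(trim_to_first_observation(f), fc$fc_mm[fc$plot_id == p], config)
  }))
  events <- detect_events(trajectories, config)
  list(canopy_daily = canopy_daily, storages = storages, fc = fc,
       trajectories = trajectories, events = events)
}
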