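#' One day of the soil-moisture-deficit bucket model
#'
#' The profile is a single store whose state is the soil moisture deficit
#' (SMD, mm below field capacity; 0 = at field capacity, larger = drier).
#' Actual evapotranspiration is potential evapotranspiration scaled by the
#' canopy cover fraction (before full closure the crop transpires less than
#' PET) and, optionally, by a linear soil-dryness stress term. The day's
#' provisional deficit is `smd_prev + aet - rain - irrigation`; any surplus
#' below zero leaves the profile as drainage and the deficit floors at 0:
#'
#' ```
#' aet      = pet * cover * stress(smd_prev)
#' d        = smd_prev + aet - rain - irrigation
#' drainage = max(0, -d)
#' smd_next = max(0, d)
#' ```
#'
#' `stress` is 1 when `stress_model = "off"`, otherwise
#' `clamp((taw - smd_prev) / (taw - raw), 0, 1)`. Evapotranspiration, water
#' addition and drainage partitioning are folded into one provisional-deficit
#' formula: at daily resolution the within-day ordering is arbitrary, so a
#' single auditable equation is preferred.
#'
#' All arguments are vectorised element-wise.
#'
#' @param smd_prev Deficit (mm, >= 0) at the end of the previous day.
#' @param rain_mm,pet_mm,irrigation_mm Daily depths (mm, >= 0).
#' @param cover Canopy cover fraction in \[0, 1\].
#' @param config A [trial_config()].
#' @return A list with numeric vectors `smd`, `aet`, `drainage`.
#' @examples
#' wb_step(10, rain_mm = 0, pet_mm = 5, irrigation_mm = 0, cover = 1)
#' @export
wb_step <- function(smd_prev, rain_mm, pet_mm, irrigation_mm = 0, cover = 1,
                    config = trial_config()) {
  stress <- if (config$stress_model == "linear") {
    clamp((config$taw_mm - smd_prev) / (config$taw_mm - config$raw_mm))
  } else {
    1
  }
  aet <- pet_mm * cover * stress
  d <- smd_prev + aet - rain_mm - irrigation_mm
  list(smd = pmax(0, d), aet = aet, drainage = pmax(0, -d))
}

#' Reset the modelled deficit to an observed storage
#'
#' Whenever a probe reading is available, the model state is overridden by
#' the observation: `smd = max(0, fc_mm - observed_storage_mm)`. The residual
#' (model prediction minus reset value) quantifies model drift since the last
#' observation. A reading wetter than field capacity resets the deficit to 0
#' and is flagged as supersaturated; no retroactive drainage is invented for
#' the excess.
#'
#' @param smd_model Modelled deficit (mm) on the observation day.
#' @param observed_storage_mm Observed profile storage (mm, >= 0).
#' @param fc_mm Field capacity (mm).
#' @return A list `smd`, `residual`, `supersaturated`.
#' @export
apply_reset <- function(smd_model, observed_storage_mm, fc_mm) {
  if (any(observed_storage_mm < 0)) {
    wb_abort("invariant", "observed_storage_mm must be >= 0")
  }
  smd <- pmax(0, fc_mm - observed_storage_mm)
  list(smd = smd, residual = smd_model - smd,
       supersaturated = observed_storage_mm > fc_mm)
}

#' Run the daily water balance for one plot
#'
#' Iterates [wb_step()] over contiguous daily forcings. On any day with an
#' observed storage the model first takes its step (so a prediction and its
#' residual exist) and the deficit is then reset via [apply_reset()] before
#' the next day. Initialisation: a numeric `smd_init` is the deficit at the
#' end of the day before the first forcing day; the default
#' `"from_first_observation"` requires an observation on the first forcing
#' day, which anchors the deficit (that day is recorded as a reset with zero
#' fluxes and no residual). Forcing days before the first observation are
#' refused rather than guessed at.
#'
#' @param forcings Tibble with columns `date` (daily, contiguous), `rain_mm`,
#'   `pet_mm`, `irrigation_mm`, `cover` and optionally
#'   `observed_storage_mm` (`NA` on days without a reading) and `plot_id`.
#' @param fc_mm Field capacity (mm) for this plot (a single number or a row
#'   of [estimate_field_capacity()] output).
#' @param config A [trial_config()].
#' @param smd_init Either a nonnegative number or `"from_first_observation"`.
#' @return A tibble (class `balance_trajectory`) with one row per forcing
#'   day: `plot_id`, `date`, the forcings, `smd_mm`, `aet_mm`, `drainage_mm`,
#'   `reset`, `reset_residual_mm`, `supersaturated`.
#' @export
run_balance <- function(forcings, fc_mm, config = trial_config(),
                        smd_init = "from_first_observation") {
  if (is.data.frame(fc_mm)) fc_mm <- fc_mm$fc_mm[1]
  n <- nrow(forcings)
  if (n == 0) wb_abort("invariant", "forcings is empty")
  if (length(missing_days(forcings$date)) || anyDuplicated(forcings$date)) {
    wb_abort("gap", "forcings must be contiguous daily with unique dates")
  }
  if (!"irrigation_mm" %in% names(forcings)) forcings$irrigation_mm <- 0
  if (!"cover" %in% names(forcings)) forcings$cover <- 0
  if (!"observed_storage_mm" %in% names(forcings)) {
    forcings$observed_storage_mm <- NA_real_
  }
  obs <- forcings$observed_storage_mm
  has_obs <- !is.na(obs)

  smd <- aet <- drain <- residual <- numeric(n)
  reset <- supersat <- logical(n)
  residual[] <- NA_real_

  start <- 1L
  if (identical(smd_init, "from_first_observation")) {
    if (!any(has_obs)) {
      wb_abort("initialization",
               "no storage observation available to anchor the initial deficit")
    }
    first_obs <- which(has_obs)[1]
    if (first_obs > 1L) {
      wb_abort("initialization", sprintf(
        "forcings begin %d day(s) before the first storage observation (%s); trim them or give a numeric smd_init",
        first_obs - 1L, format(forcings$date[first_obs])))
    }
    r <- apply_reset(NA_real_, obs[1], fc_mm)
    smd[1] <- r$smd
    reset[1] <- TRUE
    supersat[1] <- r$supersaturated
    prev <- smd[1]
    start <- 2L
  } else {
    if (!is.numeric(smd_init) || length(smd_init) != 1 || smd_init < 0) {
      wb_abort("initialization", "smd_init must be 'from_first_observation' or a single nonnegative number")
    }
    prev <- smd_init
  }

  warned_taw <- FALSE
  for (i in seq.int(start, length.out = n - start + 1L)) {
    st <- wb_step(prev, forcings$rain_mm[i], forcings$pet_mm[i],
                  forcings$irrigation_mm[i], forcings$cover[i], config)
    smd[i] <- st$smd; aet[i] <- st$aet; drain[i] <- st$drainage
    if (has_obs[i]) {
      r <- apply_reset(st$smd, obs[i], fc_mm)
      smd[i] <- r$smd
      residual[i] <- r$residual
      reset[i] <- TRUE
      supersat[i] <- r$supersaturated
    }
    if (!warned_taw && config$stress_model == "off" &&
        !is.null(config$taw_mm) && smd[i] > config$taw_mm) {
      wb_warn("deficit_exceeds_taw",
              sprintf("modelled deficit %.1f mm exceeds taw_mm = %.1f mm on %s",
                      smd[i], config$taw_mm, format(forcings$date[i])))
      warned_taw <- TRUE
    }
    prev <- smd[i]
  }

  out <- tibble(
    plot_id = if ("plot_id" %in% names(forcings)) forcings$plot_id else NA_character_,
    date = forcings$date,
    rain_mm = forcings$rain_mm, pet_mm = forcings$pet_mm,
    irrigation_mm = forcings$irrigation_mm, cover = forcings$cover,
    observed_storage_mm = obs,
    smd_mm = smd, aet_mm = aet, drainage_mm = drain,
    reset = reset, reset_residual_mm = residual, supersaturated = supersat)
  class(out) <- c("balance_trajectory", class(out))
  out
}
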