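#' Generate synthetic daily weather forcing
#'
#' A minimal stochastic weather model for a southern-hemisphere site: PET
#' follows a seasonal sinusoid peaking in mid-January (so the June--August
#' winter has the annual minimum, the low-evaporation season the
#' field-capacity estimate relies on), and rainfall is a Bernoulli wet-day
#' occurrence times gamma-distributed amounts — the simplest model with a
#' realistic dry-day structure. Defaults give roughly 640 mm annual rainfall
#' and 1000 mm annual PET, typical of an irrigated cropping site in
#' New Zealand. Identical `seed` and parameters reproduce the series
#' exactly.
#'
#' @param start,end First and last day (Date or ISO-8601 string),
#'   `start < end`.
#' @param seed Integer seed.
#' @param rain_prob Probability any day is wet. Default 0.35.
#' @param rain_mean_mm Mean rainfall (mm) on a wet day. Default 5.
#' @param rain_shape Gamma shape of wet-day amounts. Default 0.75
#'   (right-skewed, occasional large storms).
#' @param pet_mean_mm,pet_amplitude_mm Annual mean and seasonal amplitude of
#'   PET (mm/day). Defaults 2.8 and 2.2; PET is floored at 0.
#' @return A weather tibble `date`, `rain_mm`, `pet_mm`.
#' @export
generate_weather <- function(start, end, seed = 1L, rain_prob = 0.35,
                             rain_mean_mm = 5, rain_shape = 0.75,
                             pet_mean_mm = 2.8, pet_amplitude_mm = 2.2) {
  start <- as_wb_date(start, "start"); end <- as_wb_date(end, "end")
  if (start >= end) wb_abort("invariant", "need start < end")
  days <- seq(start, end, by = "day")
  doy <- as.integer(format(days, "%j"))
  # peak at mid-January (doy 15): southern-hemisphere summer maximum
  pet <- pmax(0, pet_mean_mm + pet_amplitude_mm * cos(2 * pi * (doy - 15) / 365.25))
  set.seed(as.integer(seed))
  wet <- rbinom(length(days), 1L, rain_prob)
  amounts <- rgamma(length(days), shape = rain_shape,
                    scale = rain_mean_mm / rain_shape)
  tibble(date = days, rain_mm = wet * amounts, pet_mm = pet)
}

#' Generate a complete synthetic trial with known ground truth
#'
#' Builds everything the unshared study data would have provided: weather, a
#' crop calendar (spring sowing, 42-day emergence-to-closure canopy
#' development, autumn harvest), per-plot field capacities, a ground-truth
#' run of the water balance, and sparse noisy observations of that truth —
#' fortnightly NDVI split across two instruments with a known linear
#' calibration between them, and four-weekly layered probe readings
#' (neutron-probe visits are labour-intensive, so they are sparser than
#' canopy measurements). Irrigation is rule-based: 20 mm whenever the true
#' deficit exceeds 25 mm on a November--March crop day.
#'
#' The true cover curve is the same piecewise-linear emergence-to-closure
#' ramp the canopy module assumes, NDVI observation dates are aligned with
#' emergence and closure, probe noise is drawn per layer, and NDVI noise is
#' added on the standardised scale — so with both noise scales at zero the
#' full pipeline recovers field capacity exactly and the deficit and drainage
#' trajectories to numerical precision, and with noise the recovery error is
#' attributable to the observation noise alone.
#'
#' @param n_plots Number of plots.
#' @param seed Integer seed; all randomness derives from it.
#' @param config A [trial_config()].
#' @param start,end Trial window. Defaults span two full years from a winter
#'   start.
#' @param ndvi_sd,theta_sd Observation noise s.d. on the standardised NDVI
#'   scale and on per-layer volumetric water content.
#' @param ndvi_interval_days Canopy measurement cadence. Default 14
#'   (fortnightly).
#' @param probe_interval_days Probe visit cadence. Default 28.
#' @param fc_range_mm Range (mm) from which per-plot true field capacities
#'   are drawn uniformly. Default 170--200 mm over the 60 cm profile.
#' @param closure_lag_days Days from emergence to canopy closure. Default 42
#'   (a multiple of the NDVI cadence, so closure is observed).
#' @return A list with `bundle` (a `trial_bundle` identical in shape to
#'   [read_input_tables()] output, plus the instrument `calibration` table)
#'   and `truth` (list: `fc` tibble of true field capacities, `cover` daily
#'   true cover, `trajectory` the true balance run, `ndvi_sd`, `theta_sd`).
#' @export
generate_trial <- function(n_plots = 4, seed = 1L, config = trial_config(),
                           start = "2020-07-01", end = "2022-06-30",
                           ndvi_sd = 0.03, theta_sd = 0.01,
                           ndvi_interval_days = 14, probe_interval_days = 28,
                           fc_range_mm = c(170, 200), closure_lag_days = 42,
                           ...) {
  if (n_plots < 1) wb_abort("invariant", "n_plots must be >= 1")
  start <- as_wb_date(start, "start"); end <- as_wb_date(end, "end")
  weather <- generate_weather(start, end, seed = seed, ...)
  days <- weather$date
  set.seed(as.integer(seed) + 1L)

  # calendar: sow on the first 1 October in the window, harvest next 31 March
  yr <- as.integer(format(start, "%Y"))
  sowing <- as.Date(sprintf("%d-10-01", yr))
  if (sowing < start) sowing <- as.Date(sprintf("%d-10-01", yr + 1L))
  emergence <- sowing + 10
  closure <- emergence + closure_lag_days
  harvest <- as.Date(sprintf("%d-03-31", as.integer(format(sowing, "%Y")) + 1L))
  if (harvest > end) wb_abort("invariant", "trial window too short for a crop season")

  plot_ids <- sprintf("P%02d", seq_len(n_plots))
  calendar <- tibble(plot_id = plot_ids, crop = "vegetable",
                     sowing = sowing, emergence = emergence, harvest = harvest)
  fc_true <- tibble(plot_id = plot_ids,
                    fc_mm = runif(n_plots, fc_range_mm[1], fc_range_mm[2]))

  # true daily cover: 0 / linear ramp / held at closure / 0 after harvest
  ramp <- function(d) {
    clamp(as.numeric(d - emergence) / as.numeric(closure - emergence))
  }
  cover_true_vec <- ifelse(days >= emergence & days <= harvest, ramp(days), 0)
  cover_true <- bind_rows(lapply(plot_ids, function(p) {
    tibble(plot_id = p, date = days, cover = cover_true_vec)
  }))

  # ground-truth balance with rule-based summer irrigation, per plot
  irr_rows <- list(); traj_rows <- list()
  irr_month <- month_of(days) %in% c(11L, 12L, 1L, 2L, 3L)
  in_crop <- days >= sowing & days <= harvest
  for (p in seq_len(n_plots)) {
    n <- length(days)
    smd <- aet <- drain <- irr <- numeric(n)
    prev <- 0  # winter start: profile at field capacity
    for (i in seq_len(n)) {
      if (irr_month[i] && in_crop[i] && prev > 25) irr[i] <- 20
      st <- wb_step(prev, weather$rain_mm[i], weather$pet_mm[i], irr[i],
                    cover_true_vec[i], config)
      smd[i] <- st$smd; aet[i] <- st$aet; drain[i] <- st$drainage
      prev <- smd[i]
    }
    traj_rows[[p]] <- tibble(
      plot_id = plot_ids[p], date = days,
      rain_mm = weather$rain_mm, pet_mm = weather$pet_mm,
      irrigation_mm = irr, cover = cover_true_vec,
      smd_mm = smd, aet_mm = aet, drainage_mm = drain)
    keep <- irr > 0
    irr_rows[[p]] <- tibble(plot_id = plot_ids[p], date = days[keep],
                            amount_mm = irr[keep])
  }
  truth_traj <- bind_rows(traj_rows)
  irrigation <- bind_rows(irr_rows)

  # NDVI observations: fortnightly from emergence, two instruments
  calibration <- tibble(instrument = c("greenseeker", "cropcircle"),
                        gain = c(1, 1.1), offset = c(0, -0.05))
  obs_dates <- seq(emergence, harvest, by = ndvi_interval_days)
  canopy <- bind_rows(lapply(seq_len(n_plots), function(p) {
    cov <- ramp(obs_dates)
    ndvi_std <- config$ndvi_bare + cov * (config$ndvi_closure - config$ndvi_bare) +
      rnorm(length(obs_dates), 0, ndvi_sd)
    instr <- calibration$instrument[1L + (obs_dates >= closure)]
    idx <- match(instr, calibration$instrument)
    tibble(plot_id = plot_ids[p], date = obs_dates, instrument = instr,
           ndvi_raw = clamp((ndvi_std - calibration$offset[idx]) /
                              calibration$gain[idx], -1, 1))
  }))

  # probe readings: layered, four-weekly from the trial start
  n_layers <- max(1L, as.integer(round(config$profile_depth_cm / 20)))
  layer_cm <- config$profile_depth_cm / n_layers
  probe_dates <- seq(start, end, by = probe_interval_days)
  probe <- bind_rows(lapply(seq_len(n_plots), function(p) {
    smd_p <- truth_traj$smd_mm[truth_traj$plot_id == plot_ids[p]]
    storage <- fc_true$fc_mm[p] - smd_p[match(probe_dates, days)]
    theta_bar <- storage / (config$profile_depth_cm * 10)
    bind_rows(lapply(seq_len(n_layers), function(l) {
      tibble(plot_id = plot_ids[p], date = probe_dates,
             depth_top_cm = (l - 1) * layer_cm, depth_bottom_cm = l * layer_cm,
             theta = clamp(theta_bar + rnorm(length(probe_dates), 0, theta_sd),
                           0, 0.7))
    }))
  }))

  bundle <- structure(
    list(weather = weather, canopy = canopy, probe = probe,
         irrigation = irrigation, calendar = calendar, config = config,
         fallow = fallow_intervals(calendar, weather$date, config),
         calibration = calibration),
    class = "trial_bundle")
  truth <- list(fc = fc_true, cover = cover_true, trajectory = truth_traj,
                ndvi_sd = ndvi_sd, theta_sd = theta_sd)
  list(bundle = bundle, truth = truth)
}

#' Write a trial bundle to the five input CSV files
#'
#' Writes `weather.csv`, `canopy.csv`, `probe.csv`, `irrigation.csv` and
#' `calendar.csv` into a directory in exactly the column contract
#' [read_input_tables()] reads, so a synthetic trial can exercise the whole
#' file-based pipeline. When the bundle carries truth alongside (see
#' [generate_trial()]) nothing of it is written — truth never leaks into the
#' inputs.
#'
#' @param bundle A `trial_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_trial_csvs <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(weather = file.path(dir, "weather.csv"),
             canopy = file.path(dir, "canopy.csv"),
             probe = file.path(dir, "probe.csv"),
             irrigation = file.path(dir, "irrigation.csv"),
             calendar = file.path(dir, "calendar.csv"))
  readr::write_csv(bundle$weather, paths[["weather"]], progress = FALSE)
  readr::write_csv(bundle$canopy, paths[["canopy"]], progress = FALSE)
  readr::write_csv(bundle$probe, paths[["probe"]], progress = FALSE)
  readr::write_csv(bundle$irrigation, paths[["irrigation"]], progress = FALSE)
  readr::write_csv(bundle$calendar, paths[["calendar"]], progress = FALSE)
  invisible(paths)
}
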