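# Shared fixtures and independent reference implementations.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny handcrafted valid input set (10 days of weather, 1 plot) written as
# the five CSVs; returns the named path list read_input_tables() expects.
write_tiny_inputs <- function(dir, drop_weather_date = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  days <- seq(as.Date("2021-07-01"), as.Date("2021-07-10"), by = "day")
  weather <- data.frame(date = days,
                        rain_mm = c(0, 4, 0, 0, 12, 0, 2, 0, 0, 6),
                        pet_mm = rep(0.8, 10))
  if (!is.null(drop_weather_date)) {
    weather <- weather[weather$date != as.Date(drop_weather_date), ]
  }
  canopy <- data.frame(plot_id = "A",
                       date = as.Date(c("2021-09-20", "2021-10-04")),
                       instrument = "gs", ndvi_raw = c(0.3, 0.5))
  probe <- data.frame(plot_id = "A", date = as.Date("2021-07-01"),
                      depth_top_cm = c(0, 30), depth_bottom_cm = c(30, 60),
                      theta = c(0.31, 0.29))
  irrigation <- data.frame(plot_id = "A", date = as.Date("2021-07-06"),
                           amount_mm = 5)
  calendar <- data.frame(plot_id = "A", crop = "pea",
                         sowing = as.Date("2021-09-01"),
                         emergence = as.Date("2021-09-05"),
                         harvest = as.Date("2021-12-01"))
  paths <- list(weather = file.path(dir, "weather.csv"),
                canopy = file.path(dir, "canopy.csv"),
                probe = file.path(dir, "probe.csv"),
                irrigation = file.path(dir, "irrigation.csv"),
                calendar = file.path(dir, "calendar.csv"))
  write.csv(weather, paths$weather, row.names = FALSE)
  write.csv(canopy, paths$canopy, row.names = FALSE)
  write.csv(probe, paths$probe, row.names = FALSE)
  write.csv(irrigation, paths$irrigation, row.names = FALSE)
  write.csv(calendar, paths$calendar, row.names = FALSE)
  paths
}

# Deliberately naive day-at-a-time reference for the bucket model, written
# directly from the model definition and independent of run_balance().
naive_balance <- function(forcings, fc_mm, config, smd_init) {
  n <- nrow(forcings)
  smd <- aet <- drain <- numeric(n)
  state <- smd_init
  for (i in seq_len(n)) {
    stress_factor <- 1
    if (config$stress_model == "linear") {
      stress_factor <- (config$taw_mm - state) / (config$taw_mm - config$raw_mm)
      stress_factor <- min(max(stress_factor, 0), 1)
    }
    evap <- forcings$pet_mm[i] * forcings$cover[i] * stress_factor
    deficit <- state + evap - forcings$rain_mm[i] - forcings$irrigation_mm[i]
    if (deficit < 0) {
      drain[i] <- -deficit
      deficit <- 0
    }
    if (!is.na(forcings$observed_storage_mm[i])) {
      # correction: override with the observation
      reset_to <- fc_mm - forcings$observed_storage_mm[i]
      deficit <- max(0, reset_to)
    }
    smd[i] <- deficit
    aet[i] <- evap
    state <- deficit
  }
  list(smd = smd, aet = aet, drainage = drain)
}

# Exhaustive reference segmentation of a drainage series: every positive day
# starts as its own event; adjacent events are merged to a fixpoint whenever
# the dry gap between them is within `gap`; events below `min_mm` total are
# dropped. Independent of the rle/cumsum implementation under test.
oracle_segment <- function(drainage, gap, min_mm) {
  sets <- lapply(which(drainage > 0), identity)
  repeat {
    if (length(sets) < 2) break
    merged <- FALSE
    for (k in seq_len(length(sets) - 1)) {
      if (min(sets[[k + 1]]) - max(sets[[k]]) - 1 <= gap) {
        sets[[k]] <- c(sets[[k]], sets[[k + 1]])
        sets[[k + 1]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  totals <- vapply(sets, function(s) sum(drainage[s]), numeric(1))
  keep <- totals >= min_mm
  list(start = vapply(sets[keep], min, numeric(1)),
       end = vapply(sets[keep], max, numeric(1)),
       total = totals[keep])
}

# random forcings tibble for oracle/property tests
random_forcings <- function(n_days, seed, obs_prob = 0.1) {
  set.seed(seed)
  days <- seq(as.Date("2020-01-01"), by = "day", length.out = n_days)
  tibble::tibble(
    plot_id = "X",
    date = days,
    rain_mm = rbinom(n_days, 1, 0.4) * rgamma(n_days, 0.8, scale = 7),
    pet_mm = runif(n_days, 0, 6),
    irrigation_mm = rbinom(n_days, 1, 0.05) * 20,
    cover = runif(n_days),
    observed_storage_mm = ifelse(runif(n_days) < obs_prob,
                                 runif(n_days, 100, 200), NA_real_))
}
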