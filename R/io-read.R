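#' @title Input table readers
#' @description Strict CSV readers for the five trial input tables. The column
#'   contract is fixed (snake_case names, ISO-8601 dates) and validation is
#'   total: malformed input raises a typed condition, never a silent coercion.
#' @name readers
NULL

# read a CSV and enforce the column contract; returns a tibble of the
# contract columns only, dates parsed strictly
read_contract_csv <- function(path, contract, what) {
  if (!file.exists(path)) {
    wb_abort("io", sprintf("%s file not found: '%s'", what, path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(names(contract), names(raw))
  if (length(missing)) {
    wb_abort("schema", sprintf("%s file '%s' is missing required column(s): %s",
                               what, path, paste(missing, collapse = ", ")))
  }
  out <- raw[names(contract)]
  for (col in names(contract)) {
    out[[col]] <- switch(
      contract[[col]],
      date = as_wb_date(out[[col]], sprintf("%s column '%s'", what, col)),
      double = {
        v <- suppressWarnings(as.numeric(out[[col]]))
        if (any(is.na(v) & !is.na(out[[col]]))) {
          wb_abort("schema", sprintf("%s column '%s' contains non-numeric values",
                                     what, col))
        }
        v
      },
      character = as.character(out[[col]])
    )
  }
  as_tibble(out)
}

require_no_na <- function(df, what) {
  for (col in names(df)) {
    if (anyNA(df[[col]])) {
      wb_abort("schema", sprintf("%s column '%s' contains missing values", what, col))
    }
  }
  invisible(df)
}

#' Read the daily weather forcing table
#'
#' Columns `date`, `rain_mm`, `pet_mm`. Dates must be strictly increasing and
#' contiguous (daily, no gaps); rain and PET must both be present and
#' nonnegative on every day — the balance cannot step without joint forcing.
#'
#' @param path CSV file path.
#' @return A tibble with one row per day.
#' @export
read_weather <- function(path) {
  w <- read_contract_csv(path, list(date = "date", rain_mm = "double",
                                    pet_mm = "double"), "weather")
  require_no_na(w, "weather")
  if (nrow(w) < 2) wb_abort("schema", "weather series needs at least 2 days")
  if (any(diff(as.integer(w$date)) <= 0)) {
    wb_abort("schema", "weather dates must be strictly increasing")
  }
  gaps <- missing_days(w$date)
  if (length(gaps)) {
    wb_abort("gap", sprintf("weather series has gaps; missing date(s): %s",
                            paste(format(gaps), collapse = ", ")),
             missing_dates = gaps)
  }
  if (any(w$rain_mm < 0) || any(w$pet_mm < 0)) {
    wb_abort("invariant", "weather rain_mm and pet_mm must be nonnegative")
  }
  w
}

#' Read sparse NDVI canopy observations
#'
#' Columns `plot_id`, `date`, `instrument`, `ndvi_raw`; NDVI must lie in the
#' definition range \[-1, 1\].
#'
#' @param path CSV file path.
#' @return A tibble of observations.
#' @export
read_canopy_obs <- function(path) {
  obs <- read_contract_csv(path, list(plot_id = "character", date = "date",
                                      instrument = "character",
                                      ndvi_raw = "double"), "canopy")
  require_no_na(obs, "canopy")
  bad <- which(obs$ndvi_raw < -1 | obs$ndvi_raw > 1)
  if (length(bad)) {
    wb_abort("invariant", sprintf("canopy ndvi_raw outside [-1, 1] on row(s): %s",
                                  paste(bad, collapse = ", ")))
  }
  obs
}

#' Read layered neutron-probe readings
#'
#' Columns `plot_id`, `date`, `depth_top_cm`, `depth_bottom_cm`, `theta`
#' (volumetric water content, fraction). Layers are half-open
#' `[top, bottom)` cm below the surface; for one plot and date they must not
#' overlap, and `theta` must lie in \[0, 0.7\] (porosity bound).
#'
#' @param path CSV file path.
#' @return A tibble of readings.
#' @export
read_probe_readings <- function(path) {
  pr <- read_contract_csv(path, list(plot_id = "character", date = "date",
                                     depth_top_cm = "double",
                                     depth_bottom_cm = "double",
                                     theta = "double"), "probe")
  require_no_na(pr, "probe")
  bad <- which(pr$depth_top_cm >= pr$depth_bottom_cm)
  if (length(bad)) {
    wb_abort("invariant",
             sprintf("probe layer depth_top_cm >= depth_bottom_cm on row(s): %s",
                     paste(bad, collapse = ", ")))
  }
  if (any(pr$depth_top_cm < 0)) {
    wb_abort("invariant", "probe depth_top_cm must be >= 0")
  }
  bad <- which(pr$theta < 0 | pr$theta > 0.7)
  if (length(bad)) {
    wb_abort("invariant", sprintf("probe theta outside [0, 0.7] on row(s): %s",
                                  paste(bad, collapse = ", ")))
  }
  # overlap check within plot/date
  split_keys <- paste(pr$plot_id, pr$date)
  for (k in unique(split_keys)) {
    lay <- pr[split_keys == k, ]
    lay <- lay[order(lay$depth_top_cm), ]
    if (nrow(lay) > 1 &&
        any(lay$depth_top_cm[-1] < lay$depth_bottom_cm[-nrow(lay)] - 1e-9)) {
      wb_abort("invariant", sprintf("overlapping probe layers for %s", k))
    }
  }
  pr
}

#' Read irrigation applications
#'
#' Columns `plot_id`, `date`, `amount_mm` (nonnegative depth). Several records
#' for one plot and date are legal and are summed when forcings are
#' assembled — applied depths are physically additive.
#'
#' @param path CSV file path.
#' @return A tibble of irrigation records.
#' @export
read_irrigation <- function(path) {
  ir <- read_contract_csv(path, list(plot_id = "character", date = "date",
                                     amount_mm = "double"), "irrigation")
  require_no_na(ir, "irrigation")
  if (any(ir$amount_mm < 0)) {
    wb_abort("invariant", "irrigation amount_mm must be nonnegative")
  }
  ir
}

#' Read the crop calendar
#'
#' Columns `plot_id`, `crop`, `sowing`, `emergence`, `harvest` with
#' `sowing <= emergence < harvest`; one row per plot.
#'
#' @param path CSV file path.
#' @return A tibble with one row per plot.
#' @export
read_crop_calendar <- function(path) {
  cal <- read_contract_csv(path, list(plot_id = "character", crop = "character",
                                      sowing = "date", emergence = "date",
                                      harvest = "date"), "calendar")
  require_no_na(cal, "calendar")
  if (anyDuplicated(cal$plot_id)) {
    wb_abort("invariant", "calendar must have exactly one row per plot")
  }
  bad <- which(!(cal$sowing <= cal$emergence & cal$emergence < cal$harvest))
  if (length(bad)) {
    wb_abort("invariant",
             sprintf("calendar needs sowing <= emergence < harvest; bad row(s): %s",
                     paste(bad, collapse = ", ")))
  }
  cal
}

#' Recurring winter fallow intervals for each plot
#'
#' Expands the configured fallow months over a date range into explicit
#' per-plot date intervals, excluding days inside the plot's crop interval
#' (sowing to harvest), so fallow never overlaps a growing crop.
#'
#' @param calendar Crop calendar tibble (see [read_crop_calendar()]).
#' @param range Date vector; only its min and max are used.
#' @param config A [trial_config()].
#' @return A tibble `plot_id`, `start`, `end` of non-overlapping intervals.
#' @export
fallow_intervals <- function(calendar, range, config = trial_config()) {
  days <- seq(min(range), max(range), by = "day")
  in_window <- month_of(days) %in% config$fallow_months
  out <- lapply(seq_len(nrow(calendar)), function(i) {
    crop_days <- days >= calendar$sowing[i] & days <= calendar$harvest[i]
    keep <- in_window & !crop_days
    if (!any(keep)) {
      return(tibble(plot_id = character(), start = as.Date(character()),
                    end = as.Date(character())))
    }
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(r$values)
    tibble(plot_id = calendar$plot_id[i],
           start = days[starts[idx]], end = days[ends[idx]])
  })
  bind_rows(out)
}

is_fallow_day <- function(plot_id, date, fallow) {
  out <- logical(length(date))
  f <- fallow[fallow$plot_id %in% plot_id, , drop = FALSE]
  for (i in seq_len(nrow(f))) {
    out <- out | (plot_id == f$plot_id[i] & date >= f$start[i] & date <= f$end[i])
  }
  out
}

#' Read and cross-validate the five input tables
#'
#' Reads weather, canopy, probe, irrigation and calendar CSVs, validates each
#' table's invariants, checks that every plot referenced by an observation
#' appears in the calendar, and attaches the derived winter fallow intervals.
#'
#' @param paths Named list or vector with elements `weather`, `canopy`,
#'   `probe`, `irrigation`, `calendar` giving file paths.
#' @param config A [trial_config()].
#' @return A `trial_bundle`: a list with the five validated tables, the
#'   fallow intervals and the configuration.
#' @export
read_input_tables <- function(paths, config = trial_config()) {
  need <- c("weather", "canopy", "probe", "irrigation", "calendar")
  missing <- setdiff(need, names(paths))
  if (length(missing)) {
    wb_abort("io", sprintf("paths must name the table(s): %s",
                           paste(missing, collapse = ", ")))
  }
  bundle <- list(
    weather    = read_weather(paths[["weather"]]),
    canopy     = read_canopy_obs(paths[["canopy"]]),
    probe      = read_probe_readings(paths[["probe"]]),
    irrigation = read_irrigation(paths[["irrigation"]]),
    calendar   = read_crop_calendar(paths[["calendar"]]),
    config     = config)
  known <- bundle$calendar$plot_id
  for (tab in c("canopy", "probe", "irrigation")) {
    unknown <- setdiff(unique(bundle[[tab]]$plot_id), known)
    if (length(unknown)) {
      wb_abort("reference",
               sprintf("%s table references plot(s) absent from the calendar: %s",
                       tab, paste(unknown, collapse = ", ")))
    }
  }
  bundle$fallow <- fallow_intervals(bundle$calendar, bundle$weather$date, config)
  structure(bundle, class = "trial_bundle")
}

#' @export
print.trial_bundle <- function(x, ...) {
  cat("<trial_bundle>\n")
  cat(sprintf("  %d plots, weather %s to %s (%d days)\n",
              nrow(x$calendar), format(min(x$weather$date)),
              format(max(x$weather$date)), nrow(x$weather)))
  cat(sprintf("  %d NDVI obs, %d probe readings, %d irrigation records\n",
              nrow(x$canopy), nrow(x$probe), nrow(x$irrigation)))
  invisible(x)
}
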