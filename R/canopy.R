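#' Standardise multi-instrument NDVI to a common scale
#'
#' Field campaigns often swap canopy instruments mid-season; readings are put
#' on one scale with a per-instrument linear calibration
#' `ndvi = gain * ndvi_raw + offset`. Every instrument present in the
#' observations must have a calibration row (identity is allowed); an unknown
#' instrument is an error, never silently passed through.
#'
#' @param obs Canopy observation tibble (see [read_canopy_obs()]).
#' @param calibration Tibble with columns `instrument`, `gain`, `offset`, or
#'   `NULL` for identity calibration of all instruments.
#' @return `obs` with an added `ndvi` column (standardised scale); row order
#'   and count preserved.
#' @export
standardise_ndvi <- function(obs, calibration = NULL) {
  if (is.null(calibration)) {
    calibration <- tibble(instrument = unique(obs$instrument), gain = 1, offset = 0)
  }
  unknown <- setdiff(unique(obs$instrument), calibration$instrument)
  if (length(unknown)) {
    wb_abort("calibration",
             sprintf("no calibration entry for instrument(s): %s",
                     paste(unknown, collapse = ", ")))
  }
  idx <- match(obs$instrument, calibration$instrument)
  obs$ndvi <- calibration$gain[idx] * obs$ndvi_raw + calibration$offset[idx]
  obs
}

#' Canopy cover fraction from NDVI
#'
#' Linear map between the bare-soil NDVI baseline (cover 0) and the closure
#' threshold (cover 1), clamped to \[0, 1\]:
#' `clamp((ndvi - ndvi_bare) / (ndvi_closure - ndvi_bare), 0, 1)`.
#' With defaults, cover reaches exactly 1 at NDVI 0.75 — the closure value
#' observed for well-watered vegetable crops — and 0 at or below 0.15.
#'
#' @param ndvi Numeric vector of standardised NDVI values.
#' @param config A [trial_config()].
#' @return Cover fractions in \[0, 1\], same length as `ndvi`.
#' @export
cover_fraction <- function(ndvi, config = trial_config()) {
  if (any(!is.finite(ndvi))) wb_abort("invariant", "ndvi must be finite")
  clamp((ndvi - config$ndvi_bare) / (config$ndvi_closure - config$ndvi_bare))
}

# daily cover for a single plot; obs has columns date, cover (already on the
# cover scale, per-date means, sorted, within (emergence, harvest])
interpolate_plot_cover <- function(days, obs, emergence, harvest) {
  cover <- numeric(length(days))
  in_crop <- days >= emergence & days <= harvest
  if (!any(in_crop)) return(cover)

  # knots: anchor at (emergence, 0) unless an observation sits on emergence
  if (nrow(obs) == 0) return(cover)  # no observations -> bare
  if (obs$date[1] > emergence) {
    obs <- rbind(data.frame(date = emergence, cover = 0), obs)
  }
  kd <- as.numeric(obs$date)
  kc <- obs$cover
  d <- as.numeric(days)
  val <- numeric(length(days))
  for (seg in seq_len(length(kd) - 1)) {
    sel <- d >= kd[seg] & d < kd[seg + 1]
    if (!any(sel)) next
    if (kc[seg] >= 1) {
      # closure is absorbing between observations: hold at 1 until the next
      # observation says otherwise
      val[sel] <- 1
    } else {
      val[sel] <- kc[seg] + (kc[seg + 1] - kc[seg]) *
        (d[sel] - kd[seg]) / (kd[seg + 1] - kd[seg])
    }
  }
  val[d == kd[length(kd)]] <- kc[length(kd)]
  # last observed value carried forward to harvest
  tail_sel <- d > kd[length(kd)]
  val[tail_sel] <- kc[length(kc)]
  cover[in_crop] <- clamp(val[in_crop])
  cover
}

#' Interpolate sparse canopy observations to a daily cover series
#'
#' Converts standardised NDVI to cover fractions and linearly interpolates
#' them to daily values per plot, honouring the crop stages: cover is 0
#' before emergence, after harvest and on every fallow day; development is
#' piecewise-linear in time between observations (anchored at zero cover on
#' the emergence date when no earlier observation exists); once cover reaches
#' 1 it is held there until the next observation or harvest; observed
#' declines (senescence) are followed as measured. Observations dated inside
#' a fallow interval, before emergence or after harvest are dropped with a
#' warning.
#'
#' @param obs Standardised observations (output of [standardise_ndvi()]);
#'   may cover several plots.
#' @param calendar Crop calendar tibble.
#' @param config A [trial_config()].
#' @param fallow Fallow intervals tibble (see [fallow_intervals()]); `NULL`
#'   derives them from the period and the configured fallow months.
#' @param period Date vector; the series spans `min(period)`..`max(period)`.
#'   Defaults to each plot's sowing--harvest window. Days outside a plot's
#'   crop interval always have cover 0, so a wider period only pads zeros.
#' @return A tibble `plot_id`, `date`, `cover`, daily and contiguous.
#' @export
interpolate_daily_cover <- function(obs, calendar, config = trial_config(),
                                    fallow = NULL, period = NULL) {
  if (nrow(obs) && !"ndvi" %in% names(obs)) {
    wb_abort("schema",
             "obs lacks an 'ndvi' column; run standardise_ndvi() first")
  }
  out <- vector("list", nrow(calendar))
  for (i in seq_len(nrow(calendar))) {
    pid <- calendar$plot_id[i]
    rng <- if (is.null(period)) c(calendar$sowing[i], calendar$harvest[i]) else period
    days <- seq(min(rng), max(rng), by = "day")
    fal <- if (is.null(fallow)) fallow_intervals(calendar[i, ], days, config) else fallow
    po <- obs[obs$plot_id == pid, , drop = FALSE]
    if (nrow(po)) {
      drop <- is_fallow_day(po$plot_id, po$date, fal) |
        po$date < calendar$emergence[i] | po$date > calendar$harvest[i]
      if (any(drop)) {
        wb_warn("dropped_observation",
                sprintf("plot %s: dropped %d canopy observation(s) dated in fallow or outside the crop interval",
                        pid, sum(drop)))
        po <- po[!drop, , drop = FALSE]
      }
    }
    knots <- if (nrow(po)) {
      co <- tibble(date = po$date, cover = cover_fraction(po$ndvi, config))
      co <- summarise(group_by(co, date), cover = mean(cover), .groups = "drop")
      as.data.frame(arrange(co, date))
    } else {
      data.frame(date = as.Date(character()), cover = numeric())
    }
    cov <- interpolate_plot_cover(days, knots, calendar$emergence[i],
                                  calendar$harvest[i])
    cov[is_fallow_day(rep(pid, length(days)), days, fal)] <- 0
    out[[i]] <- tibble(plot_id = pid, date = days, cover = cov)
  }
  bind_rows(out)
}
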