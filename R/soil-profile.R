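#' Aggregate layered probe readings to profile water storage
#'
#' Sums volumetric water content over the probe layers intersected with the
#' accounting profile `[0, profile_depth_cm]`:
#' `storage_mm = sum(theta_i * thickness_mm_i)`. Layer boundaries are cm
#' below the surface, half-open `[top, bottom)`; a layer reaching deeper than
#' the profile contributes only its intersected thickness. Layers must cover
#' the profile without gaps — a gap is an aggregation error naming the
#' uncovered span, because a partial profile would silently understate
#' storage.
#'
#' @param readings Probe readings tibble (see [read_probe_readings()]); may
#'   cover several plots and dates.
#' @param config A [trial_config()].
#' @return A tibble `plot_id`, `date`, `storage_mm`, one row per plot-date.
#' @export
profile_storage <- function(readings, config = trial_config()) {
  depth <- config$profile_depth_cm
  keys <- unique(readings[c("plot_id", "date")])
  keys <- arrange(keys, .data$plot_id, .data$date)
  storage <- numeric(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    lay <- readings[readings$plot_id == keys$plot_id[i] &
                      readings$date == keys$date[i], , drop = FALSE]
    lay <- lay[order(lay$depth_top_cm), ]
    tops <- pmax(lay$depth_top_cm, 0)
    bots <- pmin(lay$depth_bottom_cm, depth)
    # coverage: consecutive tops must meet previous bottoms down to `depth`
    cov_edge <- 0
    for (j in seq_len(nrow(lay))) {
      if (lay$depth_top_cm[j] >= depth) break
      if (lay$depth_top_cm[j] > cov_edge + 1e-9) {
        wb_abort("aggregation",
                 sprintf("plot %s %s: probe layers leave gap %g-%g cm within the %g cm profile",
                         keys$plot_id[i], format(keys$date[i]),
                         cov_edge, lay$depth_top_cm[j], depth))
      }
      cov_edge <- max(cov_edge, lay$depth_bottom_cm[j])
    }
    if (cov_edge < depth - 1e-9) {
      wb_abort("aggregation",
               sprintf("plot %s %s: probe layers leave gap %g-%g cm within the %g cm profile",
                       keys$plot_id[i], format(keys$date[i]), cov_edge, depth, depth))
    }
    thick_mm <- pmax(bots - tops, 0) * 10
    storage[i] <- sum(lay$theta * thick_mm)
  }
  tibble(plot_id = keys$plot_id, date = keys$date, storage_mm = storage)
}

#' Estimate field capacity from winter-fallow storages
#'
#' During the winter fallow, evaporation is minimal and rainfall keeps the
#' profile near its drained upper limit, so the profile storage observed then
#' approximates field capacity. Per plot, the estimate is either the maximum
#' winter-fallow storage (`fc_rule = "max"`, the default — the wettest fallow
#' reading) or an empirical quantile (`fc_rule = "quantile"`, a guard against
#' single outlier readings). A plot with no winter-fallow observation is an
#' estimation error: field capacity must never default silently.
#'
#' @param storages Profile storages (output of [profile_storage()]).
#' @param config A [trial_config()].
#' @param fallow Optional fallow intervals tibble; when supplied, only
#'   storages dated inside an interval for their plot are used. When `NULL`,
#'   any date whose month is in `config$fallow_months` counts as fallow.
#' @return A tibble `plot_id`, `fc_mm`, `n_obs`.
#' @export
estimate_field_capacity <- function(storages, config = trial_config(),
                                    fallow = NULL) {
  plots <- unique(storages$plot_id)
  out <- vector("list", length(plots))
  for (i in seq_along(plots)) {
    s <- storages[storages$plot_id == plots[i], , drop = FALSE]
    winter <- if (is.null(fallow)) {
      month_of(s$date) %in% config$fallow_months
    } else {
      is_fallow_day(s$plot_id, s$date, fallow)
    }
    if (!any(winter)) {
      wb_abort("estimation",
               sprintf("plot %s has no winter-fallow storage observation; field capacity cannot be estimated",
                       plots[i]))
    }
    vals <- s$storage_mm[winter]
    fc <- switch(config$fc_rule,
                 max = max(vals),
                 quantile = unname(quantile(vals, config$fc_quantile, type = 7)))
    out[[i]] <- tibble(plot_id = plots[i], fc_mm = fc, n_obs = sum(winter))
  }
  bind_rows(out)
}
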