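#' Detect discrete drainage events in a balance trajectory
#'
#' Drainage leaves the profile in bursts — after winter storms or consecutive
#' spring rainfall — and leachate sampling is scheduled around those bursts,
#' so the daily drainage series is segmented into labelled events: maximal
#' runs of days with positive drainage, with runs separated by at most
#' `event_merge_gap_days` dry days merged into one event, and merged events
#' totalling less than `event_min_mm` discarded. Events are ordered by start
#' date and labelled `<plot>-E<ordinal>`.
#'
#' @param trajectory A [run_balance()] trajectory, or any tibble with
#'   `plot_id`, `date`, `drainage_mm`; may cover several plots.
#' @param config A [trial_config()].
#' @return A tibble `plot_id`, `label`, `start_date`, `end_date`, `n_days`,
#'   `total_mm`, `peak_mm` (`n_days` counts draining days only).
#' @export
detect_events <- function(trajectory, config = trial_config()) {
  plots <- unique(trajectory$plot_id)
  out <- vector("list", length(plots))
  for (p in seq_along(plots)) {
    tr <- trajectory[trajectory$plot_id == plots[p], , drop = FALSE]
    tr <- tr[order(tr$date), ]
    seg <- segment_drainage(tr$drainage_mm, config$event_merge_gap_days,
                            config$event_min_mm)
    if (!length(seg$start)) {
      out[[p]] <- empty_events()
      next
    }
    out[[p]] <- tibble(
      plot_id = plots[p],
      label = sprintf("%s-E%d", plots[p], seq_along(seg$start)),
      start_date = tr$date[seg$start],
      end_date = tr$date[seg$end],
      n_days = seg$n_days,
      total_mm = seg$total,
      peak_mm = seg$peak)
  }
  bind_rows(out)
}

empty_events <- function() {
  tibble(plot_id = character(), label = character(),
         start_date = as.Date(character()), end_date = as.Date(character()),
         n_days = integer(), total_mm = numeric(), peak_mm = numeric())
}

# run-length segmentation of a daily drainage vector; returns a list of
# parallel vectors start/end (indices of first/last positive day), n_days
# (positive days only), total and peak, after gap-merging and minimum-total
# filtering; kept allocation-light because tests sweep it over large
# enumerations of series
segment_drainage <- function(drainage, gap_days, min_mm) {
  pos <- which(drainage > 0)
  if (!length(pos)) {
    return(list(start = integer(), end = integer(), n_days = integer(),
                total = numeric(), peak = numeric()))
  }
  # break between consecutive positive days when the dry gap exceeds gap_days
  new_event <- c(TRUE, diff(pos) > gap_days + 1L)
  starts <- pos[new_event]
  ends <- pos[c(new_event[-1], TRUE)]
  cs <- cumsum(drainage)
  total <- cs[ends] - cs[starts] + drainage[starts]
  grp <- cumsum(new_event)
  n_days <- tabulate(grp)
  peak <- vapply(seq_along(starts), function(k) {
    max(drainage[starts[k]:ends[k]])
  }, numeric(1))
  keep <- total >= min_mm
  list(start = starts[keep], end = ends[keep],
       n_days = n_days[keep], total = total[keep], peak = peak[keep])
}

#' Lag from drainage events to the next reference date
#'
#' For scheduling leachate collection: per event, the lag in whole days from
#' the event's end to the first reference date on or after it. Events with no
#' later reference date get `NA` ("none").
#'
#' @param events Output of [detect_events()].
#' @param reference_dates Nonempty vector of dates (e.g. planned sampling
#'   visits).
#' @return `events` with an added integer `lag_days` column.
#' @export
lag_days <- function(events, reference_dates) {
  if (!length(reference_dates)) {
    wb_abort("invariant", "reference_dates must be nonempty")
  }
  refs <- sort(as_wb_date(reference_dates, "reference_dates"))
  events$lag_days <- vapply(seq_len(nrow(events)), function(i) {
    nxt <- refs[refs >= events$end_date[i]]
    if (!length(nxt)) NA_integer_
    else as.integer(nxt[1] - events$end_date[i])
  }, integer(1))
  events
}

#' Seasonal summary of drainage events
#'
#' Counts and cumulative drainage grouped by plot and southern-hemisphere
#' season of the event start (winter = June--August, spring =
#' September--November, and so on).
#'
#' @param events Output of [detect_events()].
#' @return A tibble `plot_id`, `season`, `n_events`, `total_mm`; empty when
#'   there are no events.
#' @export
summarise_events <- function(events) {
  if (!nrow(events)) {
    return(tibble(plot_id = character(), season = character(),
                  n_events = integer(), total_mm = numeric()))
  }
  events$season <- season_of(events$start_date)
  out <- summarise(group_by(events, .data$plot_id, .data$season),
                   n_events = dplyr::n(), total_mm = sum(.data$total_mm),
                   .groups = "drop")
  arrange(out, .data$plot_id, .data$season)
}
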