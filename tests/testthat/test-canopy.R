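make_obs <- function(dates, ndvi, plot = "A", instrument = "gs") {
  tibble::tibble(plot_id = plot, date = as.Date(dates),
                 instrument = instrument, ndvi_raw = ndvi, ndvi = ndvi)
}

test_that("NDVI standardisation applies per-instrument linear calibration", {
  obs <- tibble::tibble(plot_id = "A", date = as.Date("2021-01-01") + 0:2,
                        instrument = c("gs", "cc", "gs"),
                        ndvi_raw = c(0.4, 0.5, 0.6))
  # identity leaves values untouched
  out <- standardise_ndvi(obs, NULL)
  expect_equal(out$ndvi, obs$ndvi_raw)

  calib <- tibble::tibble(instrument = c("gs", "cc"),
                          gain = c(1, 1.1), offset = c(0, -0.05))
  out <- standardise_ndvi(obs, calib)
  expect_equal(out$ndvi[2], 1.1 * 0.5 - 0.05)  # 0.50
  expect_equal(out$ndvi[c(1, 3)], c(0.4, 0.6))
  expect_equal(nrow(out), nrow(obs))

  err <- expect_error(standardise_ndvi(obs, calib[1, ]),
                      class = "soilwb_error_calibration")
  expect_match(conditionMessage(err), "cc")
})

test_that("cover fraction maps the bare-to-closure NDVI range onto [0, 1]", {
  cfg <- trial_config()
  expect_identical(cover_fraction(0.75, cfg), 1)    # closure
  expect_identical(cover_fraction(0.15, cfg), 0)    # bare baseline
  expect_equal(cover_fraction(0.45, cfg), 0.5)      # (0.45-0.15)/0.60
  expect_identical(cover_fraction(0.9, cfg), 1)     # clamped above
  expect_identical(cover_fraction(-0.3, cfg), 0)    # clamped below

  # non-decreasing in NDVI and bounded, over a fine grid
  grid <- seq(-1, 1, by = 0.001)
  cov <- cover_fraction(grid, cfg)
  expect_true(all(cov >= 0 & cov <= 1))
  expect_true(all(diff(cov) >= 0))
})

test_that("daily interpolation is linear between observations", {
  cfg <- trial_config()
  cal <- tibble::tibble(plot_id = "A", crop = "x",
                        sowing = as.Date("2021-10-01"),
                        emergence = as.Date("2021-10-01"),
                        harvest = as.Date("2022-01-31"))
  # cover 0 at emergence, 1 at day 30 -> 0.5 at day 15
  obs <- make_obs(cal$emergence + c(0, 30), c(0.15, 0.75))
  s <- interpolate_daily_cover(obs, cal, cfg)
  expect_equal(s$cover[s$date == cal$emergence + 15], 0.5)
  # closure is held at 1 through to harvest (no later observation)
  expect_equal(s$cover[s$date == cal$emergence + 60], 1)
  expect_equal(s$cover[s$date == cal$harvest], 1)

  # midpoint of a fortnightly segment: 0.4 at day 10, 0.6 at day 24
  obs <- make_obs(cal$emergence + c(10, 24), c(0.39, 0.51))
  s <- interpolate_daily_cover(obs, cal, cfg)
  expect_equal(s$cover[s$date == cal$emergence + 17], 0.5)
  # anchored at (emergence, 0): linear ramp toward the first observation
  expect_equal(s$cover[s$date == cal$emergence], 0)
  expect_equal(s$cover[s$date == cal$emergence + 5], 0.4 * 5 / 10)
})

test_that("interpolation respects crop stages and fallow rules", {
  cfg <- trial_config()
  cal <- tibble::tibble(plot_id = "A", crop = "x",
                        sowing = as.Date("2021-10-01"),
                        emergence = as.Date("2021-10-11"),
                        harvest = as.Date("2022-03-31"))
  period <- seq(as.Date("2021-07-01"), as.Date("2022-06-30"), by = "day")

  # no observations at all -> all-zero series
  s <- interpolate_daily_cover(make_obs(as.Date(character()), numeric()),
                               cal, cfg, period = period)
  expect_true(all(s$cover == 0))
  expect_equal(nrow(s), length(period))  # daily contiguous over the period

  obs <- make_obs(cal$emergence + c(14, 28, 42), c(0.35, 0.55, 0.75))
  s <- interpolate_daily_cover(obs, cal, cfg, period = period)
  expect_true(all(s$cover >= 0 & s$cover <= 1))
  expect_true(all(s$cover[s$date < cal$emergence] == 0))
  expect_true(all(s$cover[s$date > cal$harvest] == 0))
  # every fallow (June-August, non-crop) day is exactly zero
  june <- s$date >= as.Date("2022-06-01")
  expect_true(all(s$cover[june] == 0))
  # passes exactly through every retained observation
  expect_equal(s$cover[match(obs$date, s$date)],
               cover_fraction(obs$ndvi, cfg))
  # monotone observations give monotone cover up to closure
  ramp <- s$cover[s$date >= cal$emergence & s$date <= cal$emergence + 42]
  expect_true(all(diff(ramp) >= -1e-12))

  # an observation dated in winter fallow is dropped with a warning
  obs_bad <- rbind(obs, make_obs("2021-07-15", 0.5))
  expect_warning(s2 <- interpolate_daily_cover(obs_bad, cal, cfg, period = period),
                 class = "soilwb_warning_dropped_observation")
  expect_equal(s2$cover, s$cover)

  # observed senescence is followed down, not held at 1
  obs_sen <- make_obs(cal$emergence + c(14, 28, 42, 56, 70),
                      c(0.35, 0.55, 0.75, 0.75, 0.45))
  s3 <- interpolate_daily_cover(obs_sen, cal, cfg, period = period)
  expect_equal(s3$cover[s3$date == cal$emergence + 49], 1)  # held between 1s
  # closure is absorbing until the next observation, which is then honoured
  expect_equal(s3$cover[s3$date == cal$emergence + 63], 1)
  expect_equal(s3$cover[s3$date == cal$emergence + 70], 0.5)
  expect_equal(s3$cover[s3$date == cal$emergence + 77], 0.5)  # carried to harvest
})
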