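test_that("a single balance step follows the provisional-deficit equation", {
  s <- wb_step(10, rain_mm = 0, pet_mm = 5, irrigation_mm = 0, cover = 1)
  expect_equal(s, list(smd = 15, aet = 5, drainage = 0))

  # saturated bucket passes all surplus as drainage
  s <- wb_step(0, rain_mm = 20, pet_mm = 0)
  expect_equal(s$smd, 0); expect_equal(s$drainage, 20)

  # 5 + 1 - 3 - 4 = -1: profile refills and 1 mm drains
  s <- wb_step(5, rain_mm = 3, pet_mm = 2, irrigation_mm = 4, cover = 0.5)
  expect_equal(s, list(smd = 0, aet = 1, drainage = 1))

  # no canopy means no evapotranspiration
  expect_equal(wb_step(30, 0, 5, cover = 0)$aet, 0)
})

test_that("the linear stress model reduces transpiration as the soil dries", {
  cfg <- trial_config(stress_model = "linear", taw_mm = 100, raw_mm = 40)
  expect_equal(wb_step(20, 0, 4, cover = 1, config = cfg)$aet, 4)   # wetter than raw
  expect_equal(wb_step(70, 0, 4, cover = 1, config = cfg)$aet, 4 * 0.5)
  expect_equal(wb_step(100, 0, 4, cover = 1, config = cfg)$aet, 0)  # at taw
})

test_that("resets override the model with max(0, fc - observation)", {
  r <- apply_reset(35, 160, 180)
  expect_equal(r$smd, 20); expect_equal(r$residual, 15)
  expect_false(r$supersaturated)
  expect_equal(apply_reset(35, 180, 180)$smd, 0)  # at field capacity
  r <- apply_reset(35, 190, 180)                  # wetter than field capacity
  expect_equal(r$smd, 0); expect_true(r$supersaturated)
})

test_that("run_balance accumulates deficit and honours observation days", {
  days <- seq(as.Date("2021-01-01"), by = "day", length.out = 5)
  f <- tibble::tibble(date = days, rain_mm = 0, pet_mm = 4, irrigation_mm = 0,
                      cover = 1, observed_storage_mm = NA_real_)
  tr <- run_balance(f, fc_mm = 180, smd_init = 0)
  expect_equal(tr$smd_mm, c(4, 8, 12, 16, 20))
  expect_equal(tr$aet_mm, rep(4, 5))

  # an observation equal to fc - 7 pins that day's deficit at 7
  f$observed_storage_mm[3] <- 180 - 7
  tr <- run_balance(f, fc_mm = 180, smd_init = 0)
  expect_equal(tr$smd_mm[3], 7)
  expect_true(tr$reset[3])
  expect_equal(tr$reset_residual_mm[3], 12 - 7)  # model drift at the reset
  expect_equal(tr$smd_mm[4:5], c(11, 15))        # restarts from the reset

  # initialisation from the first observation refuses earlier days
  f$observed_storage_mm <- NA_real_
  expect_error(run_balance(f, 180), class = "soilwb_error_initialization")
  f$observed_storage_mm[3] <- 170
  expect_error(run_balance(f, 180), class = "soilwb_error_initialization")
  f$observed_storage_mm[1] <- 170
  tr <- run_balance(f, 180)
  expect_equal(tr$smd_mm[1], 10)
  expect_true(tr$reset[1])
  expect_equal(tr$aet_mm[1], 0)  # anchor day carries no model step
  expect_equal(nrow(tr), nrow(f))
})

test_that("mass balance holds at every non-reset step", {
  for (seed in 1:5) {
    f <- random_forcings(400, seed)
    tr <- run_balance(f, fc_mm = 180, trial_config(), smd_init = 30)
    d_smd <- diff(tr$smd_mm)
    rhs <- (tr$aet_mm - tr$rain_mm - tr$irrigation_mm + tr$drainage_mm)[-1]
    ok <- !tr$reset[-1]
    expect_lt(max(abs(d_smd[ok] - rhs[ok])), 1e-9)
    # bounds
    expect_true(all(tr$smd_mm >= 0))
    expect_true(all(tr$drainage_mm >= 0))
    expect_true(all(tr$aet_mm <= tr$pet_mm + 1e-12))
    # drainage only when the profile refills completely
    expect_true(all(tr$smd_mm[tr$drainage_mm > 0 & !tr$reset] == 0))
  }
})

test_that("the day loop matches an independent naive reference", {
  cfgs <- list(trial_config(),
               trial_config(stress_model = "linear", taw_mm = 120, raw_mm = 50))
  for (cfg in cfgs) {
    for (seed in 1:5) {
      f <- random_forcings(365, seed)
      tr <- run_balance(f, fc_mm = 170, cfg, smd_init = 10)
      ref <- naive_balance(f, fc_mm = 170, cfg, smd_init = 10)
      expect_identical(tr$smd_mm, ref$smd)
      expect_identical(tr$aet_mm, ref$aet)
      expect_identical(tr$drainage_mm, ref$drainage)
    }
  }
})

test_that("more rain never dries the profile nor reduces drainage", {
  set.seed(11)
  for (i in 1:200) {
    smd0 <- runif(1, 0, 80); pet <- runif(1, 0, 6); cov <- runif(1)
    rain <- sort(runif(2, 0, 40))
    lo <- wb_step(smd0, rain[1], pet, cover = cov)
    hi <- wb_step(smd0, rain[2], pet, cover = cov)
    expect_lte(hi$smd, lo$smd)
    expect_gte(hi$drainage, lo$drainage)
  }
})

test_that("with no canopy and no water input the deficit is constant", {
  days <- seq(as.Date("2021-04-01"), by = "day", length.out = 30)
  f <- tibble::tibble(date = days, rain_mm = 0, pet_mm = 5, irrigation_mm = 0,
                      cover = 0, observed_storage_mm = NA_real_)
  tr <- run_balance(f, 180, smd_init = 23)
  expect_true(all(tr$smd_mm == 23))
  expect_true(all(tr$aet_mm == 0))
  expect_true(all(tr$drainage_mm == 0))
})
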