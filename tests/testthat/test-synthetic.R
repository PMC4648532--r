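small_cfg <- function(seed = 17, ...)
  scenario_config(seed = seed, n_females = 2, n_males = 2, ...)

test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- small_cfg()
  b1 <- simulate_birds(cfg); b2 <- simulate_birds(cfg)
  expect_identical(b1, b2)
  t1 <- simulate_track(cfg, b1[1, ], 1)
  t2 <- simulate_track(cfg, b1[1, ], 1)
  expect_identical(t1, t2)
  d1 <- simulate_dives(cfg, b1[3, ], 3, dates = as.Date("2010-09-01") + 0:1)
  d2 <- simulate_dives(cfg, b1[3, ], 3, dates = as.Date("2010-09-01") + 0:1)
  expect_equal(d1$series$depth_m, d2$series$depth_m, tolerance = 1e-12)
  expect_identical(d1$series$timestamp, d2$series$timestamp)
  ## different seeds diverge
  expect_false(identical(simulate_birds(small_cfg(18)), b1))
})

test_that("cohort schedules reflect the configured sex differences", {
  cfg <- scenario_config(seed = 23, n_females = 30, n_males = 30)
  b <- simulate_birds(cfg)
  lag <- mean(as.numeric(b$departure_date[b$sex == "F"])) -
    mean(as.numeric(b$departure_date[b$sex == "M"]))
  expect_gt(lag, 4); expect_lt(lag, 10)   # ~7 d female departure lag
  expect_true(all(b$independence_date[b$sex == "M"] >
                  b$departure_date[b$sex == "M"], na.rm = TRUE))
  expect_true(all(is.na(b$dependence_days[b$sex == "F"])))
})

test_that("raw onboard tracks carry the seasonal latitude bias", {
  cfg <- small_cfg(29)
  b <- simulate_birds(cfg)[1, ]
  tr <- simulate_track(cfg, b, 1)
  ok <- !is.na(tr$raw$lat) &
    !murrelog:::in_equinox_window(tr$raw$date, filter_config()$equinox_windows)
  err_raw <- tr$raw$lat[ok] - tr$truth$lat[ok]
  ## fall (pre-equinox window) biased north, winter biased south
  fall <- as.Date(tr$raw$date[ok]) < as.Date("2010-09-09")
  winter <- as.Date(tr$raw$date[ok]) > as.Date("2010-11-01")
  expect_gt(median(err_raw[fall]), 0.5)
  expect_lt(median(err_raw[winter]), -0.5)
  ## recalculation reduces the error in both segments
  rc <- recalculate_track(tr$raw[ok, ])
  err_rc <- rc$lat - tr$truth$lat[ok]
  expect_lt(median(abs(err_rc[fall]), na.rm = TRUE), median(abs(err_raw[fall])))
  expect_lt(median(abs(err_rc[winter]), na.rm = TRUE), median(abs(err_raw[winter])))
})

test_that("noise-free twilights recalculate to the truth exactly", {
  cfg <- small_cfg(31, twilight_noise_sd_min = 0)
  b <- simulate_birds(cfg)[1, ]
  tr <- simulate_track(cfg, b, 1)
  rc <- recalculate_track(tr$raw[!is.na(tr$raw$lat), ])
  ok <- !is.na(rc$lat)
  err <- abs(rc$lat[ok] - tr$truth$lat[match(rc$date[ok], tr$truth$date)])
  expect_lt(max(err), 0.02)
})

test_that("immersion rendering honours the temperature gate and truth states", {
  cfg <- small_cfg(37)
  b <- simulate_birds(cfg)[4, ]
  im <- simulate_immersion(cfg, b, 4)
  ## all recorded temperatures are below the 28 C gate
  expect_true(all(im$series$temperature_C < 28))
  ## leg-tuck intervals produce no records
  lt <- im$truth[im$truth$state == "leg_tuck", ]
  for (i in seq_len(min(nrow(lt), 20))) {
    n_in <- sum(im$series$timestamp >= lt$start[i] & im$series$timestamp < lt$end[i])
    expect_equal(n_in, 0)
  }
  ## attendance recovery is exact in the noise-free construction
  ev <- extract_dry_events(im$series)
  att <- detect_attendance(ev, cfg$colony[["lat"]], cfg$colony[["lon"]])
  ph <- estimate_phenology(att$days, b$deployment_date)
  expect_identical(ph$departure_date, b$departure_date)
  expect_identical(ph$arrival_date, b$arrival_date)
  ## no attendance-grade dry events while at sea
  sea <- att$days[att$days > b$departure_date & att$days < b$arrival_date]
  expect_length(sea, 0)
})

test_that("every generated dive >= 3 m is detected, count exact", {
  cfg <- small_cfg(41)
  b <- simulate_birds(cfg)[3, ]
  dv <- simulate_dives(cfg, b, 3, dates = as.Date("2010-09-05") + 0:4)
  det <- detect_dives(dv$series)
  expect_equal(nrow(det$dives), nrow(dv$truth_dives))
  expect_equal(det$dives$max_depth_m, dv$truth_dives$max_depth_m, tolerance = 1e-9)
  expect_equal(det$dives$duration_s, dv$truth_dives$duration_s)
})

test_that("the true bout partition is recovered at well-separated rates", {
  cfg <- small_cfg(43, pdi = c(p = 0.75, lambda_fast = 0.05, lambda_slow = 2e-4))
  b <- simulate_birds(cfg)[3, ]
  dv <- simulate_dives(cfg, b, 3, dates = as.Date("2010-09-01") + 0:14)
  det <- detect_dives(dv$series)
  bm <- fit_bout_criterion(det$dives$pdi_s)
  out <- assign_bouts(det$dives, bm$bec_s)
  ## same-bout relation between consecutive dives matches the truth
  truth_new <- diff(dv$truth_dives$bout_id_true) > 0
  est_new <- diff(out$bout_id) > 0
  expect_gt(mean(truth_new == est_new), 0.95)
})

test_that("configured daily effort is rendered within one dive", {
  cfg <- small_cfg(47)
  b <- simulate_birds(cfg)[1, ]
  dv <- simulate_dives(cfg, b, 1, dates = as.Date("2010-09-01") + 0:4)
  expect_true(all(dv$truth_daily$rendered_min >= dv$truth_daily$target_min))
  expect_true(all(dv$truth_daily$rendered_min - dv$truth_daily$target_min < 4))
  ## daily-resolution channel matches the stage targets on average
  de <- simulate_daily_effort(cfg, b, 1,
                              dates = as.Date("2010-09-01") + 0:59)
  expect_equal(mean(de$dive_min), cfg$effort_min$MOC[["F"]], tolerance = 0.05)
})
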