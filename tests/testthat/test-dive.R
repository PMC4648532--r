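mk_pressure <- function(start, depths, step = 8) {
  data.frame(timestamp = as.POSIXct(start, tz = "UTC") + step * (seq_along(depths) - 1),
             depth_m = depths)
}

test_that("dive detection applies the 2-m run and 3-m retention rules", {
  det <- detect_dives(mk_pressure("2010-09-01 12:00:00", c(2.5, 4, 6, 4, 2.5)))
  expect_equal(nrow(det$dives), 1)
  expect_equal(det$dives$max_depth_m, 6)
  expect_equal(det$dives$duration_s, 40)
  ## a run peaking at 2.8 m is not a dive
  det2 <- detect_dives(mk_pressure("2010-09-01 12:00:00", c(2.5, 2.8, 2.5)))
  expect_equal(nrow(det2$dives), 0)
  ## two runs separated by 120 s of surface -> PDI of the first is 120 s
  s1 <- mk_pressure("2010-09-01 12:00:00", c(3, 6, 3))
  s2 <- mk_pressure("2010-09-01 12:02:16", c(4, 7, 4))
  det3 <- detect_dives(rbind(s1, s2))
  expect_equal(nrow(det3$dives), 2)
  expect_equal(det3$dives$pdi_s[1], 120)
  expect_true(is.na(det3$dives$pdi_s[2]))
  ## non-monotone timestamps are an input error
  bad <- rbind(s2, s1)
  expect_error(detect_dives(bad), "increasing")
})

test_that("bottom phase follows the 0.5 m/s velocity rule", {
  ## worked example: bottom spans samples 3..6, 24 s
  t <- seq(8, by = 8, length.out = 8)
  m <- dive_metrics(t, c(8, 16, 20, 21, 21.5, 20, 12, 4))
  expect_equal(m$bottom_time_s, 24)
  ## V-shaped dive with all |v| >= 0.5 has no bottom phase
  v <- dive_metrics(seq(0, by = 8, length.out = 7), c(8, 16, 24, 32, 24, 16, 8))
  expect_equal(v$bottom_time_s, 0)
  expect_gt(v$descent_rate_ms, 0)
  ## symmetric dive: equal descent and ascent rates
  sym <- dive_metrics(seq(0, by = 8, length.out = 9),
                      c(10, 20, 30, 30.5, 31, 30.5, 30, 20, 10))
  expect_equal(sym$descent_rate_ms, sym$ascent_rate_ms)
})

test_that("bottom time equals the brute-force velocity-scan oracle", {
  set.seed(101)
  for (k in 1:200) {
    pr <- random_dive_profile()
    m <- dive_metrics(pr$t, pr$d)
    expect_identical(m$bottom_time_s, oracle_bottom_time(pr$t, pr$d))
  }
})

test_that("bottom time never exceeds duration on detected dives", {
  cfg <- scenario_config(seed = 21, n_females = 1, n_males = 1)
  b <- simulate_birds(cfg)[2, ]
  dv <- simulate_dives(cfg, b, 2, dates = as.Date("2010-09-01") + 0:2)
  dives <- fill_dive_metrics(detect_dives(dv$series))
  expect_true(all(dives$max_depth_m >= 3))
  expect_true(all(dives$bottom_time_s <= dives$duration_s))
  expect_true(all(dives$descent_rate_ms > 0 & dives$ascent_rate_ms > 0))
})

test_that("the mixture MLE matches a dense grid-search oracle", {
  set.seed(7)
  n <- 200
  t <- ifelse(runif(n) < 0.7, rexp(n, 0.02), rexp(n, 0.001))
  fit <- fit_bout_criterion(t)
  ## optimizer must do at least as well as the dense grid (to grid error)
  expect_gt(fit$loglik, oracle_mixture_grid(t) - 1e-3)
})

test_that("bout model parameters are recovered from simulated PDIs", {
  set.seed(11)
  n <- 2000
  t <- ifelse(runif(n) < 0.7, rexp(n, 0.02), rexp(n, 0.001))
  fit <- fit_bout_criterion(t)
  expect_lt(abs(fit$p_fast - 0.7) / 0.7, 0.1)
  expect_lt(abs(fit$lambda_fast - 0.02) / 0.02, 0.1)
  expect_lt(abs(fit$lambda_slow - 0.001) / 0.001, 0.1)
  ## closed-form BEC at the true parameters
  expect_equal(bec_closed_form(0.7, 0.02, 0.001), 202.2647, tolerance = 1e-4)
  ## ... and is consistent with a numeric density-intersection root
  f <- function(t) 0.7 * 0.02 * exp(-0.02 * t) - 0.3 * 0.001 * exp(-0.001 * t)
  root <- uniroot(f, c(10, 2000), tol = 1e-9)$root
  expect_equal(bec_closed_form(0.7, 0.02, 0.001), root, tolerance = 1e-6)
})

test_that("a single exponential process is a flagged degenerate fit", {
  set.seed(13)
  expect_error(fit_bout_criterion(rexp(600, 0.01)),
               class = "murrelog_single_process")
  expect_error(fit_bout_criterion(rexp(30, 0.01)), "at least 50")
})

test_that("bout assignment splits on PDIs above the criterion", {
  dives <- data.frame(dive_id = 1:4, pdi_s = c(30, 500, 40, NA))
  out <- assign_bouts(dives, 200)
  expect_equal(out$bout_id, c(1, 1, 2, 2))
  ## all PDIs below BEC -> one bout
  expect_equal(unique(assign_bouts(data.frame(pdi_s = c(10, 20, 30)), 200)$bout_id), 1)
  ## k exceedances -> k + 1 bouts
  set.seed(5)
  pdi <- runif(300, 10, 150)
  over <- sample(299, 17)
  pdi[over] <- 500
  out2 <- assign_bouts(data.frame(pdi_s = pdi), 200)
  expect_equal(max(out2$bout_id), sum(pdi[-300] > 200) + 1)
})

test_that("IPQ is proportional to bottom time at fixed depth", {
  dives <- data.frame(max_depth_m = c(30, 30, 30, 30),
                      duration_s = c(100, 100, 100, 100),
                      bottom_time_s = c(10, 20, 0, 15),
                      bout_id = c(1, 1, 1, 1),
                      pdi_s = c(30, 30, 30, NA))
  model <- fit_duration_depth(data.frame(duration_s = c(80, 120, 160),
                                         max_depth_m = c(20, 40, 60)))
  ipq <- compute_ipq(dives, model)
  expect_equal(ipq$dives$ipq[2] / ipq$dives$ipq[1], 2)
  expect_equal(ipq$dives$ipq[3], 0)
  expect_error(compute_ipq(dives, NULL), "model")
  ## single-dive bouts are excluded from scoring
  dives2 <- dives; dives2$bout_id <- c(1, 1, 1, 2)
  ipq2 <- compute_ipq(dives2, model)
  expect_true(is.na(ipq2$dives$ipq[4]))
  expect_equal(ipq2$bouts$bout_id, 1)
})

test_that("rich patches score higher mean bout IPQ in every seeded run", {
  for (seed in c(31, 32, 33)) {
    cfg <- scenario_config(seed = seed, n_females = 1, n_males = 1)
    b <- simulate_birds(cfg)[1, ]
    dv <- simulate_dives(cfg, b, 1, dates = as.Date("2010-09-01") + 0:6)
    dives <- fill_dive_metrics(detect_dives(dv$series))
    ## use the generator's true bout partition to isolate the IPQ contrast
    dives$bout_id <- dv$truth_dives$bout_id_true
    ipq <- compute_ipq(dives, fit_duration_depth(dives))
    q_by_bout <- tapply(dv$truth_dives$patch_q, dv$truth_dives$bout_id_true, unique)
    scored <- ipq$bouts[ipq$bouts$n_dives >= 2, ]
    rich <- scored$mean_ipq[q_by_bout[as.character(scored$bout_id)] > 1]
    poor <- scored$mean_ipq[q_by_bout[as.character(scored$bout_id)] < 1]
    expect_gt(mean(rich), mean(poor))
    expect_gt(mean(rich) / mean(poor), 1.4)
  }
})

test_that("daily effort sums durations and conserves total dive time", {
  dives <- data.frame(start = as.POSIXct("2010-09-01 10:00:00", tz = "UTC") +
                        c(0, 3600, 7200),
                      duration_s = c(60, 120, 180))
  de <- daily_effort(dives)
  expect_equal(de$dive_min, 6)
  ## a dive spanning midnight is split proportionally
  dives2 <- data.frame(start = as.POSIXct("2010-09-01 23:59:00", tz = "UTC"),
                       duration_s = 120)
  de2 <- daily_effort(dives2)
  expect_equal(de2$dive_min, c(1, 1))
  expect_equal(sum(de2$dive_min) * 60, sum(dives2$duration_s))
  ## empty input with a span gives explicit zero days
  de3 <- daily_effort(dives[0, ], span = as.Date(c("2010-09-01", "2010-09-03")))
  expect_equal(de3$dive_min, c(0, 0, 0))
})

test_that("diel attribution uses the nearest position and sums to 100", {
  positions <- data.frame(date = as.Date("2010-12-01") + 0:5,
                          lat = 47, lon = -52)
  ## noon dives are day; 03:30 UTC dives are night at this longitude
  dives <- data.frame(start = c(as.POSIXct("2010-12-02 15:30:00", tz = "UTC"),
                                as.POSIXct("2010-12-02 15:40:00", tz = "UTC"),
                                as.POSIXct("2010-12-02 03:30:00", tz = "UTC")))
  ds <- diel_dive_summary(dives, positions)
  expect_identical(ds$dives$diel_phase, c("day", "day", "night"))
  expect_equal(ds$daily$pct_day + ds$daily$pct_twilight + ds$daily$pct_night, 100)
  ## dives too far from any position are unassigned
  far <- data.frame(start = as.POSIXct("2011-02-01 12:00:00", tz = "UTC"))
  ds2 <- diel_dive_summary(far, positions)
  expect_true(is.na(ds2$dives$diel_phase))
})
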