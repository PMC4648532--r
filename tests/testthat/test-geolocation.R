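test_that("longitude comes from the twilight midpoint at 15 deg per hour", {
  ## pair symmetric about Greenwich solar noon -> lon ~ 0
  d <- as.Date("2010-11-20")
  eq <- solar_ephemeris(as.POSIXct(paste(d, "12:00:00"), tz = "UTC"))$equation_of_time_min
  noon <- as.POSIXct(paste(d, "12:00:00"), tz = "UTC") - 60 * eq
  pair0 <- list(sunrise = noon - 4 * 3600, sunset = noon + 4 * 3600, polar = "none")
  expect_lt(abs(estimate_longitude(pair0)), 0.1)
  ## midpoint 4 h earlier than Greenwich solar noon -> +60 deg east
  pair60 <- list(sunrise = noon - 4 * 3600 - 4 * 3600,
                 sunset = noon + 4 * 3600 - 4 * 3600, polar = "none")
  expect_equal(estimate_longitude(pair60), 60, tolerance = 0.1)
  ## round trip through the forward model at the colony
  pair <- back_calculate_twilights("2010-12-01", 47.27, -52.77, -5)
  expect_equal(estimate_longitude(pair), -52.77, tolerance = 0.5)
})

test_that("latitude round-trips through the forward twilight model", {
  for (case in list(c(47.27, -52.77, -5), c(47.27, -52.77, -3.44),
                    c(-35, 20, -5), c(55, -45, 0))) {
    pair <- back_calculate_twilights("2010-12-01", case[1], case[2], case[3])
    expect_equal(estimate_latitude(pair, case[3]), case[1], tolerance = 1e-3)
  }
})

test_that("longitude estimates are threshold-invariant", {
  p1 <- back_calculate_twilights("2010-11-10", 50, -50, -5)
  p2 <- back_calculate_twilights("2010-11-10", 50, -50, -3.44)
  expect_lt(abs(estimate_longitude(p1) - estimate_longitude(p2)), 0.5)
})

test_that("near-equinox latitude estimation is a flagged degeneracy", {
  pair <- back_calculate_twilights("2010-09-23", 47.27, -52.77, -5)
  expect_error(estimate_latitude(pair, -5), class = "murrelog_degenerate_latitude")
})

test_that("polar positions flag rather than crash the back-calculation", {
  tw <- back_calculate_twilights("2010-12-21", 80, 0, -3.44)
  expect_identical(tw$polar, "polar_night")
  expect_error(estimate_longitude(tw), "polar")
})

test_that("recalculation corrects the onboard sun-angle latitude bias", {
  ## twilights observed at -5 deg; onboard algorithm assumes -3.44 deg
  for (case in list(list(d = "2010-08-20", lat = 50),    # fall: north bias
                    list(d = "2010-12-05", lat = 46))) { # winter: south bias
    pair <- back_calculate_twilights(case$d, case$lat, -52, -5)
    raw_lat <- estimate_latitude(pair, -3.44)
    rc <- recalculate_position(case$d, raw_lat, estimate_longitude(pair))
    expect_identical(rc$flag, "")
    expect_lt(abs(rc$lat - case$lat), 0.05)
    expect_lt(abs(rc$lat - case$lat), abs(raw_lat - case$lat))
  }
  ## equinox dates are excluded with a flag, no latitude
  rc_eq <- recalculate_position("2010-09-15", 47, -52)
  expect_identical(rc_eq$flag, "equinox_reject")
  expect_true(is.na(rc_eq$lat))
})

make_track <- function(dates, lat, lon)
  data.frame(date = as.Date(dates), lat = lat, lon = lon)

test_that("speed filter rejects an injected improbable jump", {
  days <- as.Date("2010-11-01") + 0:9
  lat <- rep(46, 10); lon <- seq(-52, -51.1, by = 0.1)
  lat[5] <- 46 + 600 / 111  # ~600 km north for one day
  fl <- filter_track(make_track(days, lat, lon))
  expect_identical(fl$rejected$flag, "speed_reject")
  expect_identical(fl$rejected$date, days[5])
  expect_equal(nrow(fl$track), 9)
})

test_that("equinox-window dates are all removed, endpoints inclusive", {
  days <- as.Date(c("2010-09-08", "2010-09-09", "2010-09-15", "2010-10-09",
                    "2010-10-10", "2011-03-06", "2011-04-06", "2011-04-07"))
  fl <- filter_track(make_track(days, rep(46, 8), rep(-52, 8)))
  expect_identical(as.character(fl$track$date),
                   c("2010-09-08", "2010-10-10", "2011-04-07"))
  expect_equal(unname(fl$report["equinox_reject"]), 5)
})

test_that("range polygon rejection works with the default box", {
  days <- as.Date("2010-11-01") + 0:2
  tr <- make_track(days, c(46, 30, 46.1), c(-52, -52, -52.05))
  fl <- filter_track(tr, filter_config(range_polygon = nw_atlantic_box()))
  expect_equal(unname(fl$report["range_reject"]), 1)
  expect_equal(nrow(fl$track), 2)
})

test_that("filtering is idempotent and matches a brute-force recount", {
  set.seed(42)
  days <- as.Date("2010-10-15") + 0:99
  lat <- 46 + cumsum(rnorm(100, 0, 0.3))
  lon <- -52 + cumsum(rnorm(100, 0, 0.4))
  viol <- sort(sample(5:95, 12))
  lat[viol] <- lat[viol] + 7  # ~780 km jumps
  tr <- make_track(days, lat, lon)
  fl1 <- filter_track(tr)
  fl2 <- filter_track(fl1$track)
  expect_identical(fl1$track, fl2$track)
  expect_equal(sum(fl2$report), 0)
  ## brute-force reapplication of the greedy speed rule
  keep <- logical(nrow(tr)); prev <- NA
  for (i in seq_len(nrow(tr))) {
    ok <- TRUE
    if (!is.na(prev)) {
      dkm <- geosphere::distHaversine(c(tr$lon[prev], tr$lat[prev]),
                                      c(tr$lon[i], tr$lat[i]), r = 6371000) / 1000
      ok <- dkm / as.numeric(tr$date[i] - tr$date[prev]) <= 500
    }
    if (ok) { keep[i] <- TRUE; prev <- i }
  }
  expect_identical(fl1$track$date, tr$date[keep])
})

test_that("an empty track yields an empty result with a warning", {
  expect_warning(fl <- filter_track(make_track(character(), numeric(), numeric())))
  expect_equal(nrow(fl$track), 0)
})
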