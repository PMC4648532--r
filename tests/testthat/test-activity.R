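mk_series <- function(start, minutes, temp = 12) {
  ts <- as.POSIXct(start, tz = "UTC") + 60 * (minutes - 1)
  data.frame(timestamp = ts, temperature_C = temp)
}

test_that("dry events are maximal runs of 60-s records", {
  ## 10 consecutive dry records -> one 10-min event
  ev <- extract_dry_events(mk_series("2010-08-01 10:00:00", 1:10))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_min, 10)
  ## 5th record suppressed by the temperature gate -> two events (4, 5 min)
  ev2 <- extract_dry_events(mk_series("2010-08-01 10:00:00", c(1:4, 6:10)))
  expect_equal(ev2$duration_min, c(4, 5))
  ## merging across the 1-min hole restores a single event
  ev3 <- extract_dry_events(mk_series("2010-08-01 10:00:00", c(1:4, 6:10)),
                            merge_gap_min = 1)
  expect_equal(nrow(ev3), 1)
  ## 361 one-minute records -> a single attendance event > 360 min
  ev4 <- extract_dry_events(mk_series("2010-08-01 06:00:00", 1:361))
  expect_equal(ev4$duration_min, 361)
  expect_identical(ev4$classification, "attendance")
  ## unsorted input is an error
  bad <- mk_series("2010-08-01 10:00:00", c(2, 1, 3))
  expect_error(extract_dry_events(bad), "sorted")
})

test_that("event durations never exceed the series span plus one cadence", {
  set.seed(3)
  mins <- sort(sample(1:500, 200))
  ev <- extract_dry_events(mk_series("2010-08-01 00:00:00", mins))
  expect_lte(sum(ev$duration_min), 500)
})

colony <- c(47.27, -52.77)

test_that("attendance days follow the 360-min and night 60-min rules", {
  ## 6 h 1 min daytime event -> attendance
  day_ev <- extract_dry_events(mk_series("2010-08-02 12:00:00", 1:361))
  att <- detect_attendance(day_ev, colony[1], colony[2])
  expect_identical(att$days, as.Date("2010-08-02"))
  ## 70-min event wholly in night -> attendance via the night rule
  night_ev <- extract_dry_events(mk_series("2010-08-03 03:00:00", 1:70))
  att2 <- detect_attendance(night_ev, colony[1], colony[2])
  expect_identical(att2$days, as.Date("2010-08-03"))
  expect_identical(att2$events$classification, "night_attendance_evidence")
  ## 300-min daytime event -> below both thresholds, no attendance
  mid_ev <- extract_dry_events(mk_series("2010-08-04 12:00:00", 1:300))
  att3 <- detect_attendance(mid_ev, colony[1], colony[2])
  expect_length(att3$days, 0)
  ## 70-min event in daylight does not qualify either
  day70 <- extract_dry_events(mk_series("2010-08-05 14:00:00", 1:70))
  expect_length(detect_attendance(day70, colony[1], colony[2])$days, 0)
})

test_that("attendance days map back to qualifying events (audit)", {
  ev <- extract_dry_events(mk_series("2010-08-02 20:00:00", 1:500))
  att <- detect_attendance(ev, colony[1], colony[2])
  ## the overnight event touches two UTC days, both audited
  expect_identical(att$days, as.Date(c("2010-08-02", "2010-08-03")))
  expect_true(all(att$audit$event == 1))
})

test_that("phenology follows the season-gap and spring rules", {
  ## attendance Aug 1-16 then nothing -> departure Aug 16
  days <- as.Date("2010-08-01") + 0:15
  ph <- estimate_phenology(days, "2010-08-01")
  expect_identical(ph$departure_date, as.Date("2010-08-16"))
  expect_true(is.na(ph$arrival_date))
  ## attendance resumes May 10 -> arrival May 10
  ph2 <- estimate_phenology(c(days, as.Date("2011-05-10") + 0:5), "2010-08-01")
  expect_identical(ph2$departure_date, as.Date("2010-08-16"))
  expect_identical(ph2$arrival_date, as.Date("2011-05-10"))
  ## a 5-day mid-August gap does not end the season
  blocks <- c(as.Date("2010-08-01") + 0:9, as.Date("2010-08-16") + 0:9)
  ph3 <- estimate_phenology(blocks, "2010-08-01")
  expect_identical(ph3$departure_date, as.Date("2010-08-25"))
  ## no attendance after deployment is an error naming the failed rule
  expect_error(estimate_phenology(as.Date("2010-07-01"), "2010-08-01"),
               "attendance")
})
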