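#' Extract uninterrupted dry events from an immersion log
#'
#' The leg-mounted logger records a dry state every 60 s while ambient
#' temperature is below 28 C; wet minutes are not logged, so the series
#' consists only of dry-minute records. A dry event is a maximal run of
#' consecutive records (60-s cadence); runs separated by gaps of at most
#' `merge_gap_min` minutes can optionally be merged. Event duration is
#' (last - first record) + 60 s. Note the temperature gate means
#' leg-tucking (dry but warm) never appears in this channel, so at-sea
#' dry events are flight candidates.
#'
#' @param series data.frame with `timestamp` (POSIXct UTC, sorted) and
#'   optionally `temperature_C`; one row per recorded dry minute.
#' @param merge_gap_min merge runs separated by gaps up to this many
#'   minutes (default 0: "uninterrupted" read literally).
#' @return data.frame of events: `start`, `end` (first/last record),
#'   `duration_min`, `n_records`, `classification` ("attendance" for
#'   events > 360 min, otherwise "flight_candidate" for events of 2-60
#'   min, else "short_dry"; night evidence is added by
#'   [detect_attendance()]).
#' @export
extract_dry_events <- function(series, merge_gap_min = 0) {
  if (nrow(series) == 0)
    return(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_min = numeric(), n_records = integer(),
                      classification = character()))
  ts <- as.POSIXct(series$timestamp, tz = "UTC")
  if (is.unsorted(as.numeric(ts)))
    stop("extract_dry_events: series must be time-sorted", call. = FALSE)
  gap_s <- diff(as.numeric(ts))
  new_run <- c(TRUE, gap_s > 60 + 60 * merge_gap_min + 1)
  run <- cumsum(new_run)
  start <- ts[!duplicated(run)]
  end <- ts[!duplicated(run, fromLast = TRUE)]
  dur <- as.numeric(difftime(end, start, units = "mins")) + 1
  ev <- data.frame(start = start, end = end, duration_min = dur,
                   n_records = as.integer(table(run)))
  ev <- ev[ev$duration_min >= 1, , drop = FALSE]
  ev$classification <- ifelse(ev$duration_min > 360, "attendance",
                              ifelse(ev$duration_min >= 2 & ev$duration_min <= 60,
                                     "flight_candidate", "short_dry"))
  rownames(ev) <- NULL
  ev
}

#' Detect colony-attendance days from dry events
#'
#' A calendar (UTC) day is an attendance day if it intersects a dry
#' event longer than 360 min (6 h), or a dry event longer than 60 min
#' whose whole span lies in night at the colony (sun below -12 deg);
#' murres do not fly at night, so long nocturnal dry spells corroborate
#' colony attendance. An event belongs to every UTC day it touches.
#'
#' @param events data.frame from [extract_dry_events()].
#' @param colony_lat,colony_lon colony coordinates (degrees).
#' @param config a [solar_config()].
#' @param attendance_min,night_min the two duration thresholds (360, 60).
#' @return list: `days` (Date vector of attendance days), `events`
#'   (input with night evidence relabelled), `audit` (data.frame mapping
#'   each attendance day to the qualifying event rows).
#' @export
detect_attendance <- function(events, colony_lat, colony_lon,
                              config = solar_config(),
                              attendance_min = 360, night_min = 60) {
  if (nrow(events) == 0)
    return(list(days = as.Date(character()), events = events,
                audit = data.frame(day = as.Date(character()), event = integer())))
  night_span <- function(start, end) {
    probes <- unique(c(start, start + as.numeric(end - start, units = "secs") / 2, end,
                       seq(start, end, by = 1800)))
    all(solar_altitude(probes, colony_lat, colony_lon) < config$night_threshold_deg)
  }
  long_ok <- events$duration_min > attendance_min
  night_ok <- !long_ok & events$duration_min > night_min &
    vapply(seq_len(nrow(events)),
           function(i) night_span(events$start[i], events$end[i]), logical(1))
  events$classification[night_ok] <- "night_attendance_evidence"
  qual <- which(long_ok | night_ok)
  audit <- do.call(rbind, lapply(qual, function(i)
    data.frame(day = seq(as.Date(events$start[i], tz = "UTC"),
                         as.Date(events$end[i], tz = "UTC"), by = "day"),
               event = i)))
  if (is.null(audit)) audit <- data.frame(day = as.Date(character()), event = integer())
  list(days = sort(unique(audit$day)), events = events, audit = audit)
}

#' Colony departure and arrival dates from attendance days
#'
#' Departure is the last attendance day followed by at least
#' `season_gap_days` days with no attendance (a shorter gap does not end
#' the season); arrival is the first attendance day on or after
#' `spring_start`. Arrival is `NA` when the log ends before any spring
#' attendance.
#'
#' @param attendance_days Date vector.
#' @param deployment_date logger deployment day; attendance before it is
#'   ignored.
#' @param season_gap_days gap defining the end of colony attendance (14).
#' @param spring_start Date from which arrival is searched (default
#'   1 March of the year after deployment).
#' @param log_end optional last day of the log, used to confirm the
#'   departure gap when the record ends quietly.
#' @return list: `departure_date`, `arrival_date` (Date or NA),
#'   `attendance_days`.
#' @export
estimate_phenology <- function(attendance_days, deployment_date,
                               season_gap_days = 14, spring_start = NULL,
                               log_end = NULL) {
  deployment_date <- as.Date(deployment_date)
  days <- sort(unique(as.Date(attendance_days)))
  days <- days[days >= deployment_date]
  if (length(days) == 0)
    stop("estimate_phenology: no attendance days on/after deployment", call. = FALSE)
  if (is.null(spring_start))
    spring_start <- as.Date(sprintf("%d-03-01",
                                    as.integer(format(deployment_date, "%Y")) + 1))
  spring_start <- as.Date(spring_start)
  pre <- days[days < spring_start]
  if (length(pre) == 0)
    stop("estimate_phenology: no attendance before the spring window; departure rule cannot apply",
         call. = FALSE)
  gaps <- diff(c(pre, spring_start))
  idx <- which(gaps > season_gap_days)
  if (length(idx) == 0) {
    if (!is.null(log_end) &&
        as.numeric(as.Date(log_end) - pre[length(pre)]) < season_gap_days)
      stop("estimate_phenology: log ends within the season gap of the last attendance day",
           call. = FALSE)
    departure <- pre[length(pre)]
  } else {
    departure <- pre[idx[length(idx)]]
    ## a gap ends the season only if no attendance follows before spring;
    ## take the last block's end (gaps < season_gap_days do not end it)
  }
  post <- days[days >= spring_start]
  arrival <- if (length(post)) post[1] else as.Date(NA)
  list(departure_date = departure, arrival_date = arrival,
       attendance_days = days)
}
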