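#' Track filtering configuration
#'
#' Defaults follow the processing rules for Lotek daily positions:
#' reject displacements implying > 500 km/day, drop calendar dates inside
#' the two equinox windows (9 Sep - 9 Oct and 6 Mar - 6 Apr, endpoints
#' inclusive; latitude from day length is uninformative near equinox) and
#' optionally restrict to an expected non-breeding range polygon.
#'
#' @param max_speed_km_per_day maximum plausible daily displacement (500).
#' @param equinox_windows list of two `c(month-day, month-day)` character
#'   pairs ("MM-DD").
#' @param range_polygon optional two-column matrix (lon, lat) of a closed
#'   polygon; positions outside are rejected. `NULL` disables the test.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(max_speed_km_per_day = 500,
                          equinox_windows = list(c("09-09", "10-09"),
                                                 c("03-06", "04-06")),
                          range_polygon = NULL) {
  stopifnot(max_speed_km_per_day > 0)
  structure(list(max_speed_km_per_day = max_speed_km_per_day,
                 equinox_windows = equinox_windows,
                 range_polygon = range_polygon),
            class = "filter_config")
}

#' Default expected non-breeding range of Northwest Atlantic murres
#'
#' A rectangular lat/lon box (38-58 N, 62-42 W) used as the default
#' range polygon for track filtering.
#' @return two-column matrix (lon, lat).
#' @export
nw_atlantic_box <- function() {
  cbind(lon = c(-62, -42, -42, -62), lat = c(38, 38, 58, 58))
}

in_equinox_window <- function(date, windows) {
  md <- format(as.Date(date), "%m-%d")
  out <- rep(FALSE, length(md))
  for (w in windows) {
    if (w[1] <= w[2]) out <- out | (md >= w[1] & md <= w[2])
    else out <- out | (md >= w[1] | md <= w[2])
  }
  out
}

## even-odd ray casting; poly is a (lon, lat) matrix, open or closed
point_in_polygon <- function(lon, lat, poly) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) { poly <- poly[-n, , drop = FALSE]; n <- n - 1 }
  vapply(seq_along(lon), function(k) {
    x <- lon[k]; y <- lat[k]; inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi) inside <- !inside
      j <- i
    }
    inside
  }, logical(1))
}

#' Longitude from a twilight pair
#'
#' The midpoint of sunrise and sunset is local solar noon; longitude is
#' read off the offset of that midpoint from 12:00 UTC after correcting
#' for the equation of time (15 degrees per hour, west negative).
#'
#' @param pair list with POSIXct `sunrise` and `sunset` (UTC); a `polar`
#'   element other than "none" is an error.
#' @return longitude in decimal degrees.
#' @export
estimate_longitude <- function(pair) {
  if (!is.null(pair$polar) && pair$polar != "none")
    stop("estimate_longitude: undefined for polar day/night", call. = FALSE)
  mid <- pair$sunrise + as.numeric(difftime(pair$sunset, pair$sunrise, units = "secs")) / 2
  eq <- solar_ephemeris(mid)$equation_of_time_min
  lt <- as.POSIXlt(mid, tz = "UTC")
  m <- lt$hour * 60 + lt$min + lt$sec / 60
  lon <- (720 - eq - m) / 4
  ((lon + 180) %% 360) - 180
}

#' Latitude from day length at a known sun angle
#'
#' Solves for the latitude whose modelled day length (interval between
#' threshold crossings at `sun_angle_deg`, via [twilight_times()])
#' matches the observed sunrise-to-sunset interval. The day-length
#' equation `cos H = (sin a0 - sin phi sin delta) / (cos phi cos delta)`
#' is monotone in latitude away from the equinoxes, so the root is
#' unique; it is found by bisection over [-70, 70].
#'
#' @param pair twilight pair (list with `sunrise`, `sunset`).
#' @param sun_angle_deg threshold at which the twilights were observed.
#' @param lat_range search interval, default `c(-70, 70)`.
#' @param tol bisection tolerance in degrees.
#' @return latitude in decimal degrees.
#' @export
estimate_latitude <- function(pair, sun_angle_deg, lat_range = c(-70, 70),
                              tol = 1e-4) {
  if (!is.null(pair$polar) && pair$polar != "none")
    stop("estimate_latitude: polar twilight pair", call. = FALSE)
  mid <- pair$sunrise + as.numeric(difftime(pair$sunset, pair$sunrise, units = "secs")) / 2
  decl <- solar_ephemeris(mid)$declination_deg
  if (abs(decl) < 1)
    stop(structure(class = c("murrelog_degenerate_latitude", "error", "condition"),
                   list(message = "estimate_latitude: near-equinox declination, day length uninformative",
                        call = NULL)))
  date <- as.Date(mid)
  lon <- estimate_longitude(pair)
  obs <- as.numeric(difftime(pair$sunset, pair$sunrise, units = "mins"))
  f <- function(phi) {
    tw <- twilight_times(date, phi, lon, sun_angle_deg)
    if (tw$polar == "polar_night") return(0 - obs)
    if (tw$polar == "polar_day") return(1440 - obs)
    as.numeric(difftime(tw$sunset, tw$sunrise, units = "mins")) - obs
  }
  flo <- f(lat_range[1]); fhi <- f(lat_range[2])
  if (sign(flo) == sign(fhi))
    stop(structure(class = c("murrelog_no_latitude_solution", "error", "condition"),
                   list(message = "estimate_latitude: no solution in latitude range",
                        call = NULL)))
  uniroot(f, lat_range, tol = tol)$root
}

#' Back-calculate a twilight pair from a daily position
#'
#' Reconstructs the sunrise/sunset times consistent with a position,
#' date and sun-angle threshold -- the inverse of the onboard
#' algorithm's position step at its built-in -3.44 deg angle.
#'
#' @param date calendar day.
#' @param lat,lon position in decimal degrees.
#' @param sun_angle_deg threshold, default -3.44 (the onboard angle).
#' @return twilight pair as from [twilight_times()], with
#'   `sun_angle_deg` recorded.
#' @export
back_calculate_twilights <- function(date, lat, lon, sun_angle_deg = -3.44) {
  tw <- twilight_times(as.Date(date), lat, lon, sun_angle_deg)
  tw$sun_angle_deg <- sun_angle_deg
  tw$date <- as.Date(date)
  tw
}

#' Recalculate a raw onboard position
#'
#' Applies the sun-angle bias correction: (1) back-calculate twilight
#' times from the raw position at the onboard angle of -3.44 deg, then
#' (2) re-estimate latitude from the implied day length at the true sun
#' angle of -5 deg. Longitude comes from the twilight midpoint and is
#' unchanged to within rounding. Dates inside the equinox windows are
#' flagged `equinox_reject` and no latitude is emitted.
#'
#' @param date calendar day of the raw fix.
#' @param lat,lon raw onboard position.
#' @param config a [solar_config()] supplying the two sun angles.
#' @param equinox_windows as in [filter_config()].
#' @return one-row data.frame (date, lat, lon, source, flag).
#' @export
recalculate_position <- function(date, lat, lon, config = solar_config(),
                                 equinox_windows = filter_config()$equinox_windows) {
  date <- as.Date(date)
  if (in_equinox_window(date, equinox_windows))
    return(data.frame(date = date, lat = NA_real_, lon = lon,
                      source = "recalculated", flag = "equinox_reject"))
  pair <- back_calculate_twilights(date, lat, lon, config$onboard_sun_angle_deg)
  if (pair$polar != "none")
    return(data.frame(date = date, lat = NA_real_, lon = NA_real_,
                      source = "recalculated", flag = pair$polar))
  new_lat <- tryCatch(estimate_latitude(pair, config$true_sun_angle_deg),
                      error = function(e) NA_real_)
  flag <- if (is.na(new_lat)) "degenerate_latitude" else ""
  data.frame(date = date, lat = new_lat, lon = estimate_longitude(pair),
             source = "recalculated", flag = flag)
}

#' Recalculate every position of a raw track
#'
#' @param track data.frame with columns `date`, `lat`, `lon` (raw
#'   onboard daily positions).
#' @inheritParams recalculate_position
#' @return data.frame of recalculated positions (one row per input row).
#' @export
recalculate_track <- function(track, config = solar_config(),
                              equinox_windows = filter_config()$equinox_windows) {
  out <- do.call(rbind, lapply(seq_len(nrow(track)), function(i)
    recalculate_position(track$date[i], track$lat[i], track$lon[i],
                         config, equinox_windows)))
  if ("bird_id" %in% names(track)) out <- cbind(bird_id = track$bird_id, out)
  out
}

#' Filter a daily position track
#'
#' Sequentially (in date order) removes positions that (1) fall in an
#' equinox window, (2) lie outside the range polygon (if configured), or
#' (3) imply a great-circle speed above `max_speed_km_per_day` relative
#' to the previous *retained* fix (greedy forward pass). Haversine
#' distances use a 6371 km mean Earth radius. Filtering is idempotent.
#'
#' @param track data.frame with `date`, `lat`, `lon`, sorted by date.
#' @param config a [filter_config()].
#' @return list with `track` (retained rows), `rejected` (rows with a
#'   `flag` column) and `report` (named counts per rejection reason).
#' @export
filter_track <- function(track, config = filter_config()) {
  if (nrow(track) == 0) {
    warning("filter_track: empty track")
    return(list(track = track, rejected = track,
                report = c(equinox_reject = 0, range_reject = 0, speed_reject = 0)))
  }
  if (is.unsorted(as.Date(track$date)))
    stop("filter_track: track must be sorted by date", call. = FALSE)
  track$date <- as.Date(track$date)
  flag <- rep("", nrow(track))
  usable <- !is.na(track$lat) & !is.na(track$lon)
  flag[!usable] <- "missing"
  flag[usable & in_equinox_window(track$date, config$equinox_windows)] <- "equinox_reject"
  if (!is.null(config$range_polygon)) {
    idx <- which(flag == "")
    out_rng <- !point_in_polygon(track$lon[idx], track$lat[idx], config$range_polygon)
    flag[idx[out_rng]] <- "range_reject"
  }
  prev <- NA_integer_
  for (i in which(flag == "")) {
    if (!is.na(prev)) {
      d_km <- geosphere::distHaversine(c(track$lon[prev], track$lat[prev]),
                                       c(track$lon[i], track$lat[i]),
                                       r = 6371000) / 1000
      dt <- as.numeric(track$date[i] - track$date[prev])
      if (dt > 0 && d_km / dt > config$max_speed_km_per_day) {
        flag[i] <- "speed_reject"
        next
      }
    }
    prev <- i
  }
  keep <- flag == ""
  rejected <- track[!keep, , drop = FALSE]
  rejected$flag <- flag[!keep]
  report <- c(equinox_reject = sum(flag == "equinox_reject"),
              range_reject = sum(flag == "range_reject"),
              speed_reject = sum(flag == "speed_reject"),
              missing = sum(flag == "missing"))
  list(track = track[keep, , drop = FALSE], rejected = rejected, report = report)
}
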