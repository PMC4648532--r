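#' Solar geometry configuration
#'
#' Thresholds (degrees of solar altitude) used throughout the pipeline:
#' the diel-phase boundaries (0 deg day / -12 deg night, i.e. nautical
#' twilight), the logger's built-in sun angle (-3.44 deg) and the true
#' sun angle (-5 deg) used for latitude re-estimation.
#'
#' @param day_threshold_deg altitude at or above which it is day (0).
#' @param night_threshold_deg altitude below which it is night (-12).
#' @param onboard_sun_angle_deg threshold assumed by the logger's onboard
#'   position algorithm (-3.44).
#' @param true_sun_angle_deg threshold at which twilights are actually
#'   observed (-5); latitudes are re-estimated at this angle.
#' @return a list of class `solar_config`.
#' @export
solar_config <- function(day_threshold_deg = 0,
                         night_threshold_deg = -12,
                         onboard_sun_angle_deg = -3.44,
                         true_sun_angle_deg = -5) {
  cfg <- list(day_threshold_deg = day_threshold_deg,
              night_threshold_deg = night_threshold_deg,
              onboard_sun_angle_deg = onboard_sun_angle_deg,
              true_sun_angle_deg = true_sun_angle_deg)
  stopifnot(night_threshold_deg < true_sun_angle_deg,
            true_sun_angle_deg < onboard_sun_angle_deg,
            onboard_sun_angle_deg < day_threshold_deg,
            all(unlist(cfg) >= -18), all(unlist(cfg) <= 6))
  structure(cfg, class = "solar_config")
}

## Low-precision solar ephemeris: solar declination and equation of time
## from the standard closed-form series in Julian centuries (geometric
## mean longitude, mean anomaly, equation of center, mean obliquity).
## Accurate to ~0.01 deg / ~0.1 min over 1990-2050 -- far inside the
## 100-200 km positional error of threshold geolocation.
solar_ephemeris <- function(time) {
  jd <- as.numeric(as.POSIXct(time, tz = "UTC")) / 86400 + 2440587.5
  T <- (jd - 2451545) / 36525
  deg2rad <- pi / 180
  L0 <- (280.46646 + 36000.76983 * T + 0.0003032 * T^2) %% 360
  M <- (357.52911 + 35999.05029 * T - 0.0001537 * T^2) * deg2rad
  e <- 0.016708634 - 0.000042037 * T - 0.0000001267 * T^2
  C <- (1.914602 - 0.004817 * T - 0.000014 * T^2) * sin(M) +
    (0.019993 - 0.000101 * T) * sin(2 * M) + 0.000289 * sin(3 * M)
  true_long <- L0 + C
  omega <- (125.04 - 1934.136 * T) * deg2rad
  lambda <- (true_long - 0.00569 - 0.00478 * sin(omega)) * deg2rad
  eps0 <- 23 + 26 / 60 + 21.448 / 3600 -
    (46.815 * T + 0.00059 * T^2 - 0.001813 * T^3) / 3600
  eps <- (eps0 + 0.00256 * cos(omega)) * deg2rad
  decl <- asin(sin(eps) * sin(lambda))
  y <- tan(eps / 2)^2
  L0r <- L0 * deg2rad
  eq <- y * sin(2 * L0r) - 2 * e * sin(M) + 4 * e * y * sin(M) * cos(2 * L0r) -
    0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * M)
  list(declination_deg = decl / deg2rad,
       equation_of_time_min = 4 * eq / deg2rad)
}

#' Geometric solar altitude
#'
#' Sun altitude above the horizon (degrees), without atmospheric
#' refraction; the pipeline's altitude thresholds absorb refraction.
#'
#' @param time POSIXct (UTC) instant(s).
#' @param lat,lon position in decimal degrees (west negative).
#' @return altitude in degrees, vectorised over `time`.
#' @export
solar_altitude <- function(time, lat, lon) {
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    stop("solar_altitude: coordinates out of range", call. = FALSE)
  eph <- solar_ephemeris(time)
  lt <- as.POSIXlt(time, tz = "UTC")
  minutes <- lt$hour * 60 + lt$min + lt$sec / 60
  ## true solar time in minutes, hour angle in degrees
  tst <- (minutes + eph$equation_of_time_min + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  phi <- lat * pi / 180
  dec <- eph$declination_deg * pi / 180
  sin_alt <- sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(ha * pi / 180)
  asin(pmin(1, pmax(-1, sin_alt))) * 180 / pi
}

#' Twilight (threshold-crossing) times for a date and position
#'
#' Instants at which the sun crosses `threshold_deg` rising and setting
#' on the local solar day, solved by the hour-angle formula with two
#' refinement iterations of the ephemeris at the event time.
#'
#' @param date a `Date` (or coercible) calendar day.
#' @param lat,lon decimal degrees.
#' @param threshold_deg solar altitude defining the transition.
#' @return list with `sunrise`, `sunset` (POSIXct UTC or NA) and `polar`
#'   (one of "none", "polar_day", "polar_night").
#' @export
twilight_times <- function(date, lat, lon, threshold_deg = 0) {
  stopifnot(threshold_deg >= -18, threshold_deg <= 6)
  date <- as.Date(date)
  noon_guess <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC")
  half_day <- function(at) {
    eph <- solar_ephemeris(at)
    phi <- lat * pi / 180
    dec <- eph$declination_deg * pi / 180
    a0 <- threshold_deg * pi / 180
    cosH <- (sin(a0) - sin(phi) * sin(dec)) / (cos(phi) * cos(dec))
    list(cosH = cosH, eqtime = eph$equation_of_time_min)
  }
  hd <- half_day(noon_guess)
  if (hd$cosH > 1)
    return(list(sunrise = as.POSIXct(NA), sunset = as.POSIXct(NA), polar = "polar_night"))
  if (hd$cosH < -1)
    return(list(sunrise = as.POSIXct(NA), sunset = as.POSIXct(NA), polar = "polar_day"))
  solar_noon <- function(eqtime)
    as.POSIXct(date, tz = "UTC") + 60 * (720 - 4 * lon - eqtime)
  noon <- solar_noon(hd$eqtime)
  H_min <- 4 * acos(hd$cosH) * 180 / pi   # half day length in minutes
  sunrise <- noon - 60 * H_min
  sunset <- noon + 60 * H_min
  for (i in 1:2) {  # refine with ephemeris at the event itself
    hr <- half_day(sunrise); hs <- half_day(sunset)
    if (hr$cosH > 1 || hs$cosH > 1)
      return(list(sunrise = as.POSIXct(NA), sunset = as.POSIXct(NA), polar = "polar_night"))
    if (hr$cosH < -1 || hs$cosH < -1)
      return(list(sunrise = as.POSIXct(NA), sunset = as.POSIXct(NA), polar = "polar_day"))
    sunrise <- solar_noon(hr$eqtime) - 240 * acos(hr$cosH) * 180 / pi
    sunset <- solar_noon(hs$eqtime) + 240 * acos(hs$cosH) * 180 / pi
  }
  list(sunrise = sunrise, sunset = sunset, polar = "none")
}

#' Diel phase of an instant
#'
#' Classifies instants as day (altitude >= 0), twilight (-12 <= altitude
#' < 0, nautical) or night (altitude < -12). Boundary convention: 0 is
#' day, -12 is twilight.
#'
#' @param time POSIXct UTC instant(s).
#' @param lat,lon decimal degrees.
#' @param config a [solar_config()].
#' @return character vector in `c("day", "twilight", "night")`.
#' @export
diel_phase <- function(time, lat, lon, config = solar_config()) {
  alt <- solar_altitude(time, lat, lon)
  ifelse(alt >= config$day_threshold_deg, "day",
         ifelse(alt >= config$night_threshold_deg, "twilight", "night"))
}
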