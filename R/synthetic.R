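#' Scenario configuration for synthetic logger deployments
#'
#' Defaults are the study conditions this pipeline was built around:
#' a Witless Bay (Gull Island) colony at 47.27 N, 52.77 W; male colony
#' departure preceding the female's by about a week; offspring
#' dependence drawn from N(62.8, 8.9) days; daily foraging effort of
#' about 96 min/day for independent females versus 174 min/day for
#' single-parenting males during male-only care; post-dive intervals
#' from a two-process exponential mixture (p = 0.7, lambda_fast = 0.02,
#' lambda_slow = 0.001 per second); twilights observed at a -5 deg sun
#' angle with 2 min timing noise while the onboard algorithm assumes
#' -3.44 deg.
#'
#' @param seed integer seed; every generated record is reproducible
#'   from it.
#' @param n_females,n_males cohort sizes per sex.
#' @param colony `c(lat, lon)` of the colony.
#' @param deployment_date logger deployment day.
#' @param male_departure_offset_days mean/sd days from deployment to
#'   male colony departure.
#' @param female_departure_lag_days mean/sd days the female departs
#'   after the male.
#' @param male_arrival_date nominal male spring arrival; `arrival_sd_days`
#'   jitters it and `female_arrival_lag_days` delays females.
#' @param arrival_sd_days sd of arrival jitter.
#' @param female_arrival_lag_days mean/sd female arrival lag.
#' @param dependence_days mean/sd of offspring dependence (days at sea).
#' @param effort_min named list per stage of `c(F, M)` target daily
#'   accumulated dive time (min/day).
#' @param effort_cv coefficient of variation of day-to-day effort.
#' @param depth_mean named list per stage of `c(F, M)` mean dive depth (m).
#' @param depth_sd sd of dive depth (m).
#' @param pdi `c(p, lambda_fast, lambda_slow)` of the PDI mixture.
#' @param descent_rate_ms,ascent_rate_ms vertical transit rates.
#' @param bottom_base_s `c(a, b)`: baseline bottom time a + b * depth.
#' @param patch_rich_q,patch_poor_q,patch_rich_prob bout-level patch
#'   quality multipliers on baseline bottom time and the probability a
#'   bout is rich.
#' @param twilight_noise_sd_min sd of twilight timing noise (minutes).
#' @param step_km daily random-walk step scale of the movement model.
#' @param moc_center,npc_center `c(lat, lon)` attractors of the
#'   post-departure and winter areas.
#' @param range_box `c(lat_min, lat_max, lon_min, lon_max)` bounding the
#'   walk.
#' @param track_end,pressure_end last day of the position/pressure logs.
#' @param n_chick_lost_males how many males lose their chick at fledging
#'   (female-like effort throughout; flagged).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1,
                            n_females = 6, n_males = 6,
                            colony = c(lat = 47.27, lon = -52.77),
                            deployment_date = "2010-07-20",
                            male_departure_offset_days = c(mean = 14, sd = 4),
                            female_departure_lag_days = c(mean = 7, sd = 2),
                            male_arrival_date = "2011-05-10",
                            arrival_sd_days = 4,
                            female_arrival_lag_days = c(mean = 6, sd = 3),
                            dependence_days = c(mean = 62.8, sd = 8.9),
                            effort_min = list(BPC = c(F = 113.4, M = 118.6),
                                              MOC = c(F = 96.1, M = 174.2),
                                              NPC = c(F = 125.2, M = 122.1)),
                            effort_cv = 0.08,
                            depth_mean = list(BPC = c(F = 50.0, M = 58.6),
                                              MOC = c(F = 35.5, M = 48.6),
                                              NPC = c(F = 51.6, M = 50.2)),
                            depth_sd = 12,
                            pdi = c(p = 0.7, lambda_fast = 0.02, lambda_slow = 0.001),
                            descent_rate_ms = 1.2, ascent_rate_ms = 1.2,
                            bottom_base_s = c(a = 10, b = 0.5),
                            patch_rich_q = 1.3, patch_poor_q = 0.7,
                            patch_rich_prob = 0.5,
                            twilight_noise_sd_min = 2,
                            step_km = 40,
                            moc_center = c(lat = 44.5, lon = -51.5),
                            npc_center = c(lat = 45.5, lon = -50.5),
                            range_box = c(38, 58, -62, -42),
                            track_end = "2011-01-31",
                            pressure_end = "2011-01-31",
                            n_chick_lost_males = 0) {
  stopifnot(seed == as.integer(seed), twilight_noise_sd_min >= 0,
            pdi[["lambda_fast"]] > pdi[["lambda_slow"]],
            pdi[["p"]] > 0, pdi[["p"]] < 1)
  cfg <- as.list(environment())
  structure(cfg, class = "scenario_config")
}

## per-bird, per-channel reproducible seed (kept below 2^31)
bird_seed <- function(config, bird_index, channel) {
  base <- as.numeric(config$seed) %% 1e6
  as.integer((base * 1009 + bird_index * 131 + channel * 7919) %% 2147483587 + 1)
}

#' Draw the cohort's ground-truth life-history schedule
#'
#' One row per bird: sex, departure/arrival dates, offspring-dependence
#' duration for males (independence date), chick-lost flag.
#'
#' @param config a [scenario_config()].
#' @return data.frame of class `deployment_truth` metadata.
#' @export
simulate_birds <- function(config) {
  set.seed(bird_seed(config, 0, 1))
  dep <- as.Date(config$deployment_date)
  n <- config$n_females + config$n_males
  sex <- c(rep("F", config$n_females), rep("M", config$n_males))
  male_dep <- dep + round(stats::rnorm(n, config$male_departure_offset_days[["mean"]],
                                       config$male_departure_offset_days[["sd"]]))
  lag <- round(stats::rnorm(n, config$female_departure_lag_days[["mean"]],
                            config$female_departure_lag_days[["sd"]]))
  departure <- as.Date(ifelse(sex == "M", male_dep, male_dep + pmax(1, lag)),
                       origin = "1970-01-01")
  departure <- pmax(departure, dep + 3)
  arr0 <- as.Date(config$male_arrival_date) +
    round(stats::rnorm(n, 0, config$arrival_sd_days))
  alag <- round(stats::rnorm(n, config$female_arrival_lag_days[["mean"]],
                             config$female_arrival_lag_days[["sd"]]))
  arrival <- as.Date(ifelse(sex == "M", arr0, arr0 + pmax(0, alag)),
                     origin = "1970-01-01")
  dependence <- pmax(30, round(stats::rnorm(n, config$dependence_days[["mean"]],
                                            config$dependence_days[["sd"]])))
  chick_lost <- rep(FALSE, n)
  if (config$n_chick_lost_males > 0) {
    males <- which(sex == "M")
    chick_lost[males[seq_len(min(config$n_chick_lost_males, length(males)))]] <- TRUE
  }
  data.frame(bird_id = sprintf("%s%02d", sex, stats::ave(seq_len(n), sex, FUN = seq_along)),
             sex = sex, deployment_date = dep, departure_date = departure,
             arrival_date = arrival,
             dependence_days = ifelse(sex == "M" & !chick_lost, dependence, NA),
             independence_date = as.Date(ifelse(sex == "M" & !chick_lost,
                                                departure + dependence, NA),
                                         origin = "1970-01-01"),
             chick_lost = chick_lost)
}

## stage of a calendar day for effort/depth lookups
day_stage <- function(date, departure) {
  date <- as.Date(date)
  year <- as.integer(format(as.Date(departure), "%Y"))
  npc_start <- as.Date(sprintf("%d-11-01", year))
  ifelse(date <= as.Date(departure), "BPC",
         ifelse(date < npc_start, "MOC", "NPC"))
}

## male daily effort target: MOC-male level while the chick depends on
## him, female-like after independence (or throughout if chick lost)
effort_target <- function(config, sex, date, departure, independence, chick_lost) {
  st <- day_stage(date, departure)
  if (st != "MOC") return(config$effort_min[[st]][[sex]])
  if (sex == "F") return(config$effort_min$MOC[["F"]])
  if (chick_lost || (!is.na(independence) && as.Date(date) >= as.Date(independence)))
    return(config$effort_min$MOC[["F"]])
  config$effort_min$MOC[["M"]]
}

#' Simulate a bird's true track and raw onboard positions
#'
#' The true daily positions follow a bounded drift-plus-noise walk:
#' colony-bound during bi-parental care, drifting to the offshore
#' post-departure area, then the winter area from 1 November. For each
#' day, twilights are observed at the true -5 deg sun angle with
#' Gaussian timing noise, and the raw onboard position is computed from
#' those twilights under the onboard -3.44 deg assumption (longitude
#' from the twilight midpoint, latitude from day length), reproducing
#' the documented fall-north / winter-south latitude bias.
#'
#' @param config a [scenario_config()].
#' @param bird one row of [simulate_birds()].
#' @param bird_index integer index used for seeding.
#' @return list: `truth` (date, lat, lon), `twilights` (date, sunrise,
#'   sunset; noisy, as observed), `raw` (date, lat, lon, source, flag;
#'   the onboard positions, NA lat where the onboard solver fails).
#' @export
simulate_track <- function(config, bird, bird_index = 1) {
  set.seed(bird_seed(config, bird_index, 2))
  days <- seq(as.Date(bird$deployment_date), as.Date(config$track_end), by = "day")
  dep_date <- as.Date(bird$departure_date)
  year <- as.integer(format(dep_date, "%Y"))
  npc_start <- as.Date(sprintf("%d-11-01", year))
  lat <- numeric(length(days)); lon <- numeric(length(days))
  lat[1] <- config$colony[["lat"]]; lon[1] <- config$colony[["lon"]]
  for (i in seq_along(days)[-1]) {
    d <- days[i]
    if (d <= dep_date) {
      lat[i] <- config$colony[["lat"]] + stats::rnorm(1, 0, 0.05)
      lon[i] <- config$colony[["lon"]] + stats::rnorm(1, 0, 0.07)
    } else {
      target <- if (d < npc_start) config$moc_center else config$npc_center
      km_lat <- 111.32
      km_lon <- 111.32 * cos(lat[i - 1] * pi / 180)
      pull <- 0.15
      lat[i] <- lat[i - 1] + pull * (target[["lat"]] - lat[i - 1]) +
        stats::rnorm(1, 0, config$step_km / sqrt(2)) / km_lat
      lon[i] <- lon[i - 1] + pull * (target[["lon"]] - lon[i - 1]) +
        stats::rnorm(1, 0, config$step_km / sqrt(2)) / km_lon
      lat[i] <- min(max(lat[i], config$range_box[1]), config$range_box[2])
      lon[i] <- min(max(lon[i], config$range_box[3]), config$range_box[4])
    }
  }
  noise_s <- config$twilight_noise_sd_min * 60
  sunrise <- .POSIXct(rep(NA_real_, length(days)), tz = "UTC")
  sunset <- .POSIXct(rep(NA_real_, length(days)), tz = "UTC")
  raw_lat <- rep(NA_real_, length(days)); raw_lon <- rep(NA_real_, length(days))
  flag <- character(length(days))
  cfg_solar <- solar_config()
  for (i in seq_along(days)) {
    tw <- twilight_times(days[i], lat[i], lon[i], cfg_solar$true_sun_angle_deg)
    if (tw$polar != "none") { flag[i] <- tw$polar; next }
    sunrise[i] <- tw$sunrise + stats::rnorm(1, 0, noise_s)
    sunset[i] <- tw$sunset + stats::rnorm(1, 0, noise_s)
    pair <- list(sunrise = sunrise[i], sunset = sunset[i], polar = "none")
    raw_lon[i] <- estimate_longitude(pair)
    raw_lat[i] <- tryCatch(
      estimate_latitude(pair, cfg_solar$onboard_sun_angle_deg),
      error = function(e) NA_real_)
    if (is.na(raw_lat[i])) flag[i] <- "onboard_failed"
  }
  list(truth = data.frame(date = days, lat = lat, lon = lon),
       twilights = data.frame(date = days, sunrise = sunrise, sunset = sunset),
       raw = data.frame(date = days, lat = raw_lat, lon = raw_lon,
                        source = "raw_onboard", flag = flag))
}

#' Simulate a bird's immersion (dry-record) channel
#'
#' Renders a behavioural-state schedule to 60-s dry records under the
#' 28 C recording gate: overnight colony-attendance bouts (> 6 h dry)
#' on every colony night from deployment to departure and again from
#' spring arrival to the log end; short daytime flights at sea
#' (2-45 min dry); night-time leg-tucking (dry but warm, so suppressed
#' by the gate -- present in the truth schedule, absent from the
#' records); wet foraging/rest otherwise (never logged).
#'
#' @inheritParams simulate_track
#' @param immersion_end last day of the immersion log; default 10 days
#'   after arrival (memory limits truncated many real spring logs).
#' @return list: `series` (timestamp, temperature_C; one row per
#'   recorded dry minute), `truth` (state, start, end intervals).
#' @export
simulate_immersion <- function(config, bird, bird_index = 1,
                               immersion_end = NULL) {
  set.seed(bird_seed(config, bird_index, 3))
  dep <- as.Date(bird$deployment_date)
  departure <- as.Date(bird$departure_date)
  arrival <- as.Date(bird$arrival_date)
  if (is.null(immersion_end)) immersion_end <- arrival + 10
  immersion_end <- as.Date(immersion_end)
  states <- list()
  add_state <- function(state, start, end)
    states[[length(states) + 1]] <<- data.frame(state = state, start = start, end = end)
  ## overnight attendance bouts: night of day d into day d+1
  colony_nights <- c(seq(dep, departure - 1, by = "day"),
                     if (arrival <= immersion_end - 1)
                       seq(arrival, immersion_end - 1, by = "day"))
  for (d in as.list(colony_nights)) {
    start <- as.POSIXct(paste(d, "21:00:00"), tz = "UTC") +
      round(stats::runif(1, -60, 60)) * 60
    dur_h <- stats::runif(1, 9, 13)
    add_state("attendance", start, start + round(dur_h * 60) * 60)
  }
  ## at-sea days: flights (dry, cold) and leg-tucks (dry, warm: gated out)
  sea_days <- seq(departure + 1, min(immersion_end, arrival - 1), by = "day")
  for (d in as.list(sea_days)) {
    n_fl <- stats::rpois(1, 2)
    if (n_fl > 0) {
      starts <- as.POSIXct(paste(d, "12:00:00"), tz = "UTC") +
        round(stats::runif(n_fl, 0, 7 * 60)) * 60
      for (k in seq_len(n_fl)) {
        dur <- round(stats::runif(1, 2, 45))
        add_state("flight", starts[k], starts[k] + dur * 60)
      }
    }
    if (stats::runif(1) < 0.6) {
      lt_start <- as.POSIXct(paste(d, "02:00:00"), tz = "UTC") +
        round(stats::runif(1, 0, 120)) * 60
      add_state("leg_tuck", lt_start, lt_start + round(stats::runif(1, 60, 240)) * 60)
    }
  }
  truth <- do.call(rbind, states)
  truth <- truth[order(truth$start), ]
  rownames(truth) <- NULL
  recorded <- truth[truth$state %in% c("attendance", "flight"), , drop = FALSE]
  ts_list <- lapply(seq_len(nrow(recorded)), function(i)
    seq(recorded$start[i], recorded$end[i] - 1, by = 60))
  ts <- as.POSIXct(unlist(ts_list), origin = "1970-01-01", tz = "UTC")
  ts <- sort(unique(ts))
  series <- data.frame(timestamp = ts,
                       temperature_C = pmin(27.5, stats::rnorm(length(ts), 12, 3)))
  list(series = series, truth = truth)
}

## render one dive as 8-s samples below the 2-m recording threshold;
## returns depths vector and true bottom seconds used
render_dive <- function(max_depth, bottom_s, desc_rate, asc_rate, sample_s = 8) {
  step_d <- desc_rate * sample_s
  step_a <- asc_rate * sample_s
  desc <- if (max_depth >= 2 + step_d) seq(2 + step_d, max_depth, by = step_d) else numeric()
  if (length(desc) == 0 || desc[length(desc)] < max_depth - 1e-9) desc <- c(desc, max_depth)
  n_bot <- max(1, round(bottom_s / sample_s))
  bot <- max_depth - stats::runif(n_bot, 0, 0.4)
  asc <- if (max_depth >= 2 + step_a) rev(seq(2 + step_a, max_depth, by = step_a)) else numeric()
  if (length(asc) && asc[1] >= max_depth - 1e-9) asc <- asc[-1]
  pmax(c(desc, bot, asc), 2.01)
}

#' Simulate a bird's pressure (dive) channel
#'
#' Dives are arranged in bouts: after each dive the post-dive interval
#' is drawn from the two-process exponential mixture (fast = within
#' bout, slow = starts a new bout), snapped to the 8-s sampling grid
#' with a 24-s floor so consecutive dives remain separable. Depths are
#' drawn per sex and stage; true bottom time is a bout-level patch
#' quality multiplier (rich/poor) on a depth-dependent baseline;
#' profiles are rendered at 8-s cadence below the 2-m recording
#' threshold. Dives accumulate each day until the day's configured
#' effort target (with day-to-day noise) is met, so measured daily
#' effort matches the configured level to within one dive.
#'
#' @inheritParams simulate_track
#' @param dates optional Date vector restricting which days get dives
#'   (default: day after departure through `config$pressure_end`).
#' @return list: `series` (timestamp, depth_m), `truth_dives` (per-dive
#'   start, max depth, true bottom time, true bout id, patch quality),
#'   `truth_daily` (date, target_min, rendered_min).
#' @export
simulate_dives <- function(config, bird, bird_index = 1, dates = NULL) {
  set.seed(bird_seed(config, bird_index, 4))
  if (is.null(dates))
    dates <- seq(as.Date(bird$departure_date) + 1, as.Date(config$pressure_end),
                 by = "day")
  p <- config$pdi[["p"]]; lf <- config$pdi[["lambda_fast"]]; ls <- config$pdi[["lambda_slow"]]
  sample_s <- 8
  all_ts <- list(); all_depth <- list(); truth <- list(); daily <- list()
  bout_counter <- 0
  for (d in as.list(dates)) {
    st <- day_stage(d, bird$departure_date)
    target <- effort_target(config, bird$sex, d, bird$departure_date,
                            bird$independence_date, bird$chick_lost)
    target <- max(10, stats::rnorm(1, target, config$effort_cv * target))
    target_s <- target * 60
    t_now <- as.POSIXct(paste(d, "05:00:00"), tz = "UTC") +
      round(stats::runif(1, 0, 450)) * sample_s
    acc <- 0
    bout_counter <- bout_counter + 1
    q <- if (stats::runif(1) < config$patch_rich_prob) config$patch_rich_q else config$patch_poor_q
    while (acc < target_s) {
      depth <- min(120, max(3.5, stats::rnorm(1, config$depth_mean[[st]][[bird$sex]],
                                              config$depth_sd)))
      bottom <- q * (config$bottom_base_s[["a"]] + config$bottom_base_s[["b"]] * depth)
      depths <- render_dive(depth, bottom, config$descent_rate_ms,
                            config$ascent_rate_ms, sample_s)
      n <- length(depths)
      ts <- t_now + sample_s * (seq_len(n) - 1)
      all_ts[[length(all_ts) + 1]] <- as.numeric(ts)
      all_depth[[length(all_depth) + 1]] <- depths
      truth[[length(truth) + 1]] <-
        data.frame(date = d, start = ts[1], max_depth_m = max(depths),
                   duration_s = n * sample_s, bottom_s_true = bottom,
                   bout_id_true = bout_counter, patch_q = q)
      acc <- acc + n * sample_s
      fast <- stats::runif(1) < p
      gap <- stats::rexp(1, if (fast) lf else ls)
      if (!fast) gap <- min(gap, 1800)  # keep the day's session inside the day
      gap <- max(3 * sample_s, round(gap / sample_s) * sample_s)
      if (!fast) {
        bout_counter <- bout_counter + 1
        q <- if (stats::runif(1) < config$patch_rich_prob) config$patch_rich_q else config$patch_poor_q
      }
      t_now <- ts[n] + sample_s + gap
    }
    daily[[length(daily) + 1]] <- data.frame(date = d, target_min = target,
                                             rendered_min = acc / 60)
  }
  series <- data.frame(timestamp = as.POSIXct(unlist(all_ts), origin = "1970-01-01",
                                              tz = "UTC"),
                       depth_m = unlist(all_depth))
  list(series = series,
       truth_dives = do.call(rbind, truth),
       truth_daily = do.call(rbind, daily))
}

#' Simulate daily accumulated dive time directly
#'
#' The daily-resolution counterpart of [simulate_dives()]: draws each
#' day's accumulated dive time from the configured sex/stage target with
#' the configured day-to-day noise, without rendering 8-s profiles.
#' Used for cohort-scale stage analyses where only the daily effort
#' series matters.
#'
#' @inheritParams simulate_dives
#' @return data.frame (date, dive_min).
#' @export
simulate_daily_effort <- function(config, bird, bird_index = 1, dates = NULL) {
  set.seed(bird_seed(config, bird_index, 5))
  if (is.null(dates))
    dates <- seq(as.Date(bird$departure_date) + 1, as.Date(config$pressure_end),
                 by = "day")
  target <- vapply(as.list(dates), function(d)
    effort_target(config, bird$sex, d, bird$departure_date,
                  bird$independence_date, bird$chick_lost), numeric(1))
  data.frame(date = dates,
             dive_min = pmax(0, stats::rnorm(length(dates), target,
                                             config$effort_cv * target)))
}

#' Simulate a complete cohort deployment
#'
#' Generates every logger channel plus ground truth for each bird in
#' the scenario. Channels can be switched off to keep large cohorts
#' light.
#'
#' @param config a [scenario_config()].
#' @param channels subset of `c("track", "immersion", "dives")`.
#' @return list: `config`, `birds` (truth metadata), and per-bird lists
#'   under `track`, `immersion`, `dives` keyed by bird id.
#' @export
simulate_deployment <- function(config,
                                channels = c("track", "immersion", "dives")) {
  birds <- simulate_birds(config)
  out <- list(config = config, birds = birds,
              track = list(), immersion = list(), dives = list())
  for (i in seq_len(nrow(birds))) {
    b <- birds[i, ]
    if ("track" %in% channels) out$track[[b$bird_id]] <- simulate_track(config, b, i)
    if ("immersion" %in% channels)
      out$immersion[[b$bird_id]] <- simulate_immersion(config, b, i)
    if ("dives" %in% channels) out$dives[[b$bird_id]] <- simulate_dives(config, b, i)
  }
  out
}
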