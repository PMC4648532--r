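#' Pipeline configuration
#'
#' Collects every numeric threshold the processing chain uses, each
#' defaulting to its standard value: the solar/diel thresholds and the
#' two sun angles, the 28 C immersion recording gate, the 360-min and
#' 60-min attendance rules, the 3 m dive retention and 2 m recording
#' thresholds, the 0.5 m/s bottom-phase velocity rule, the 500 km/day
#' speed filter and equinox windows, the 25-min PDI summary cap, the
#' 50 km kernel grid, stage constants and the fractionation table.
#' Round-trips unchanged through YAML serialization.
#'
#' @param seed integer seed recorded with every run.
#' @param ... overrides for any default element.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    solar = unclass(solar_config()),
    immersion_gate_C = 28,
    attendance_min = 360,
    night_attendance_min = 60,
    season_gap_days = 14,
    dive_min_depth_m = 3,
    dive_record_threshold_m = 2,
    dive_sample_s = 8,
    bottom_velocity_ms = 0.5,
    pdi_summary_cap_min = 25,
    max_speed_km_per_day = 500,
    equinox_windows = list(c("09-09", "10-09"), c("03-06", "04-06")),
    grid_km = 50,
    bandwidth = "lscv",
    core_level = 0.5,
    female_bpc_offset_days = 7,
    independence_window_days = 5,
    independence_k_consecutive = 7,
    fractionation = fractionation_table()
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_pipeline_config` returns the restored config.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$fractionation <- as.data.frame(raw$fractionation)
  raw$seed <- as.integer(raw$seed)
  raw$equinox_windows <- lapply(raw$equinox_windows, unlist)
  structure(raw, class = "pipeline_config")
}

#' Hash of a configuration (stamped into outputs)
#' @param config a `pipeline_config`.
#' @return md5 string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_pipeline_config(config, tf)
  unname(tools::md5sum(tf))
}

read_csv_checked <- function(path, required, timestamp_cols = character()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing mandatory column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  n_bad <- 0
  for (col in timestamp_cols) {
    parsed <- as.POSIXct(strptime(df[[col]], "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
    alt <- is.na(parsed)
    if (any(alt))
      parsed[alt] <- as.POSIXct(strptime(df[[col]][alt], "%Y-%m-%d %H:%M:%S",
                                         tz = "UTC"))
    bad <- is.na(parsed) & !is.na(df[[col]])
    n_bad <- n_bad + sum(bad)
    df[[col]] <- parsed
    df <- df[!bad, , drop = FALSE]
  }
  attr(df, "n_malformed") <- n_bad
  if (nrow(df) == 0) warning(sprintf("%s: empty series", basename(path)))
  df
}

#' Read the standard logger channels for one bird
#'
#' Immersion CSV: (bird_id, timestamp, temperature_C); pressure CSV:
#' (bird_id, timestamp, depth_m); positions CSV: (bird_id, date, lat,
#' lon, source). Timestamps are ISO-8601 UTC; malformed rows are
#' dropped and counted; a missing mandatory column is a hard error.
#'
#' @param immersion_path,pressure_path,positions_path file paths
#'   (`NULL` to skip a channel).
#' @return list with `immersion`, `pressure`, `positions` data.frames
#'   (each carrying an `n_malformed` attribute) or NULL.
#' @export
read_channels <- function(immersion_path = NULL, pressure_path = NULL,
                          positions_path = NULL) {
  out <- list(immersion = NULL, pressure = NULL, positions = NULL)
  if (!is.null(immersion_path))
    out$immersion <- read_csv_checked(immersion_path, c("timestamp", "temperature_C"),
                                      "timestamp")
  if (!is.null(pressure_path))
    out$pressure <- read_csv_checked(pressure_path, c("timestamp", "depth_m"),
                                     "timestamp")
  if (!is.null(positions_path)) {
    out$positions <- read_csv_checked(positions_path, c("date", "lat", "lon"))
    out$positions$date <- as.Date(out$positions$date)
  }
  for (nm in names(out))
    if (!is.null(out[[nm]]) && "timestamp" %in% names(out[[nm]]))
      out[[nm]] <- out[[nm]][order(out[[nm]]$timestamp), , drop = FALSE]
  out
}

#' Write a synthetic deployment's channels as CSV
#'
#' @param deployment list from [simulate_deployment()].
#' @param dir output directory; `truth/` receives the ground-truth
#'   tables.
#' @return `dir`, invisibly.
#' @export
write_deployment <- function(deployment, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  fmt_t <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(deployment$birds, file.path(dir, "truth", "birds.csv"),
                   row.names = FALSE)
  for (id in names(deployment$immersion)) {
    s <- deployment$immersion[[id]]$series
    utils::write.csv(data.frame(bird_id = id, timestamp = fmt_t(s$timestamp),
                                temperature_C = s$temperature_C),
                     file.path(dir, paste0(id, "_immersion.csv")), row.names = FALSE)
  }
  for (id in names(deployment$dives)) {
    s <- deployment$dives[[id]]$series
    utils::write.csv(data.frame(bird_id = id, timestamp = fmt_t(s$timestamp),
                                depth_m = s$depth_m),
                     file.path(dir, paste0(id, "_pressure.csv")), row.names = FALSE)
    utils::write.csv(deployment$dives[[id]]$truth_dives,
                     file.path(dir, "truth", paste0(id, "_dives.csv")),
                     row.names = FALSE)
  }
  for (id in names(deployment$track)) {
    utils::write.csv(deployment$track[[id]]$raw,
                     file.path(dir, paste0(id, "_positions.csv")), row.names = FALSE)
    utils::write.csv(deployment$track[[id]]$truth,
                     file.path(dir, "truth", paste0(id, "_track.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

process_one_bird <- function(bird, channels, config, colony) {
  out <- list(bird_id = bird$bird_id, sex = bird$sex)
  scfg <- do.call(solar_config, config$solar)
  ## positions: recalculate raw onboard fixes, then filter
  if (!is.null(channels$positions)) {
    rc <- recalculate_track(channels$positions, scfg, config$equinox_windows)
    fl <- filter_track(rc, filter_config(config$max_speed_km_per_day,
                                         config$equinox_windows))
    out$positions <- fl$track
    out$position_report <- fl$report
  }
  ## immersion: dry events -> attendance -> phenology
  if (!is.null(channels$immersion) && nrow(channels$immersion) > 0) {
    ev <- extract_dry_events(channels$immersion)
    att <- detect_attendance(ev, colony[1], colony[2], scfg,
                             config$attendance_min, config$night_attendance_min)
    out$dry_events <- att$events
    out$phenology <- tryCatch(
      estimate_phenology(att$days, bird$deployment_date, config$season_gap_days),
      error = function(e) NULL)
  }
  ## pressure: dives -> metrics -> bouts -> IPQ -> effort -> diel
  if (!is.null(channels$pressure) && nrow(channels$pressure) > 0) {
    det <- detect_dives(channels$pressure, config$dive_min_depth_m,
                        config$dive_record_threshold_m, config$dive_sample_s)
    dives <- fill_dive_metrics(det, config$bottom_velocity_ms)
    bm <- tryCatch(fit_bout_criterion(dives$pdi_s), error = function(e) NULL)
    if (!is.null(bm)) {
      dives <- assign_bouts(dives, bm$bec_s)
      ipq <- compute_ipq(dives, fit_duration_depth(dives))
      dives <- ipq$dives
      out$bouts <- ipq$bouts
      out$bout_model <- bm
    }
    out$dives <- dives
    out$daily_effort <- daily_effort(dives)
    if (!is.null(out$positions) && nrow(out$positions) > 0)
      out$diel <- diel_dive_summary(dives, out$positions, scfg)$daily
  }
  out
}

#' Run the full per-deployment pipeline
#'
#' Chains geolocation (recalculate + filter), activity/phenology, dive
#' analytics (detection, metrics, per-bird bout criterion, bouts, IPQ,
#' daily effort, diel attribution), stage delineation with
#' offspring-independence estimation, per-sex/stage kernel core areas
#' with overlap, and isotope adjustment. Failures are isolated per bird
#' and tabulated; the run log records seed and config hash.
#'
#' @param deployment a [simulate_deployment()] result, or a list with
#'   the same shape built from [read_channels()] output.
#' @param config a [pipeline_config()].
#' @param isotope_samples optional isotope sample table.
#' @return list of report tables: `phenology`, `stage_windows`,
#'   `daily_effort`, `dive_summary`, `overlap`, `isotopes`, `failures`,
#'   `log`.
#' @export
run_pipeline <- function(deployment, config = pipeline_config(),
                         isotope_samples = NULL) {
  birds <- deployment$birds
  colony <- if (inherits(deployment$config, "scenario_config"))
    c(deployment$config$colony[["lat"]], deployment$config$colony[["lon"]])
  else c(47.27, -52.77)
  results <- list(); failures <- list()
  for (i in seq_len(nrow(birds))) {
    b <- birds[i, ]
    channels <- list(
      positions = if (!is.null(deployment$track[[b$bird_id]]))
        deployment$track[[b$bird_id]]$raw else NULL,
      immersion = if (!is.null(deployment$immersion[[b$bird_id]]))
        deployment$immersion[[b$bird_id]]$series else NULL,
      pressure = if (!is.null(deployment$dives[[b$bird_id]]))
        deployment$dives[[b$bird_id]]$series else NULL)
    res <- tryCatch(process_one_bird(b, channels, config, colony),
                    error = function(e) {
                      failures[[b$bird_id]] <<- conditionMessage(e)
                      NULL
                    })
    if (!is.null(res)) results[[b$bird_id]] <- res
  }
  ## phenology table (Table-2-like layout)
  phen <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$phenology)) return(NULL)
    data.frame(bird_id = r$bird_id, sex = r$sex,
               departure_date = r$phenology$departure_date,
               arrival_date = r$phenology$arrival_date)
  }))
  ## female effort reference, then stages + independence per male
  fem_eff <- lapply(results, function(r)
    if (r$sex == "F" && !is.null(r$daily_effort)) r$daily_effort else NULL)
  fem_eff <- Filter(Negate(is.null), fem_eff)
  fem_ref <- if (length(fem_eff) >= 3) female_effort_reference(fem_eff) else NULL
  stages <- do.call(rbind, lapply(results, function(r) {
    dep_row <- birds[birds$bird_id == r$bird_id, ]
    if (is.null(r$phenology)) return(NULL)
    ind <- NA
    if (r$sex == "M" && !is.null(fem_ref) && !is.null(r$daily_effort)) {
      est <- tryCatch(
        estimate_independence(r$daily_effort, r$phenology$departure_date, fem_ref,
                              config$independence_window_days,
                              config$independence_k_consecutive),
        error = function(e) NULL)
      if (!is.null(est) && est$resolved) ind <- est$independence_date
    }
    log_end <- if (!is.null(r$daily_effort) && nrow(r$daily_effort))
      max(as.Date(r$daily_effort$date)) else as.Date(dep_row$arrival_date)
    sw <- tryCatch(
      delineate_stages(r$sex, dep_row$deployment_date, r$phenology$departure_date,
                       log_end, independence_date = ind,
                       female_bpc_offset_days = config$female_bpc_offset_days),
      error = function(e) NULL)
    if (is.null(sw)) return(NULL)
    cbind(bird_id = r$bird_id, sex = r$sex, sw,
          independence_days = if (!is.na(ind))
            as.numeric(as.Date(ind) - r$phenology$departure_date) else NA,
          chick_lost = dep_row$chick_lost)
  }))
  ## per-bird daily effort long table
  eff <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$daily_effort)) return(NULL)
    cbind(bird_id = r$bird_id, sex = r$sex, r$daily_effort)
  }))
  ## dive summary per bird (Table-4-like metrics, bout means)
  dive_sum <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$dives) || nrow(r$dives) == 0) return(NULL)
    d <- r$dives
    pdi_ok <- d$pdi_s[!is.na(d$pdi_s) & d$pdi_s <= config$pdi_summary_cap_min * 60]
    data.frame(bird_id = r$bird_id, sex = r$sex, n_dives = nrow(d),
               mean_depth_m = mean(d$max_depth_m),
               mean_bottom_s = mean(d$bottom_time_s[d$bottom_time_s > 0]),
               mean_descent_ms = mean(d$descent_rate_ms),
               mean_ascent_ms = mean(d$ascent_rate_ms),
               mean_pdi_s = if (length(pdi_ok)) mean(pdi_ok) else NA,
               bec_s = if (!is.null(r$bout_model)) r$bout_model$bec_s else NA,
               mean_bout_ipq = if (!is.null(r$bouts)) mean(r$bouts$mean_ipq) else NA)
  }))
  ## sex-pooled core areas and overlap for MOC and NPC
  overlap <- NULL
  pos_all <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$positions)) return(NULL)
    cbind(sex = r$sex, bird_id = r$bird_id, r$positions)
  }))
  if (!is.null(pos_all) && !is.null(stages)) {
    overlap <- do.call(rbind, lapply(c("MOC", "NPC"), function(stg) {
      sel <- merge(pos_all, stages[stages$stage == stg,
                                   c("bird_id", "start", "end")], by = "bird_id")
      sel <- sel[sel$date >= sel$start & sel$date <= sel$end, ]
      f <- sel[sel$sex == "F", ]; m <- sel[sel$sex == "M", ]
      if (nrow(f) < 10 || nrow(m) < 10) return(NULL)
      ctr <- c(mean(sel$lat), mean(sel$lon))
      ud_f <- fit_kernel_ud(f, config$grid_km, config$bandwidth, center = ctr)
      ud_m <- fit_kernel_ud(m, config$grid_km, config$bandwidth, center = ctr)
      cf <- core_contour(ud_f, config$core_level)
      cm <- core_contour(ud_m, config$core_level)
      ov <- overlap_hr(cf, cm)
      data.frame(stage = stg, n_f = length(unique(f$bird_id)),
                 n_m = length(unique(m$bird_id)),
                 area_f_km2 = cf$area_km2, area_m_km2 = cm$area_km2,
                 hr_fm = ov$hr_fm, hr_mf = ov$hr_mf,
                 mean_overlap = ov$mean_overlap)
    }))
  }
  iso <- if (!is.null(isotope_samples))
    isotope_group_summary(adjust_fractionation(isotope_samples, config$fractionation))
  else NULL
  list(phenology = phen, stage_windows = stages, daily_effort = eff,
       dive_summary = dive_sum, overlap = overlap, isotopes = iso,
       failures = failures,
       log = list(seed = config$seed, config_hash = config_hash(config),
                  n_birds = nrow(birds), timestamp_utc = format(Sys.time(), tz = "UTC"),
                  package_version = as.character(utils::packageVersion("murrelog"))))
}
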