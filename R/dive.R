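#' Detect dives in a pressure log
#'
#' The logger samples depth every 8 s while submerged below 2 m, so a
#' dive is a maximal run of consecutive samples (gaps > 16 s break a
#' run, the bird having surfaced). Runs are retained as dives only if
#' maximum depth reaches `min_depth_m` (3 m). Duration is
#' (last - first sample) + 8 s, approximating the surface crossings;
#' the post-dive interval (PDI) is the time from a dive's end to the
#' next dive's start.
#'
#' @param series data.frame with `timestamp` (POSIXct UTC, sorted) and
#'   `depth_m`.
#' @param min_depth_m retention threshold on maximum depth (3).
#' @param record_threshold_m the logger's recording threshold (2);
#'   shallower samples are discarded as noise.
#' @param sample_s sampling interval (8).
#' @return list: `dives` (data.frame dive_id, start, end, max_depth_m,
#'   duration_s, pdi_s) and `samples` (retained samples with a
#'   `dive_id` column for metric computation).
#' @export
detect_dives <- function(series, min_depth_m = 3, record_threshold_m = 2,
                         sample_s = 8) {
  ts <- as.POSIXct(series$timestamp, tz = "UTC")
  if (is.unsorted(as.numeric(ts), strictly = TRUE))
    stop("detect_dives: timestamps must be strictly increasing", call. = FALSE)
  keep <- series$depth_m >= record_threshold_m
  ts <- ts[keep]; depth <- series$depth_m[keep]
  empty <- list(dives = data.frame(dive_id = integer(), start = as.POSIXct(character(), tz = "UTC"),
                                   end = as.POSIXct(character(), tz = "UTC"),
                                   max_depth_m = numeric(), duration_s = numeric(),
                                   pdi_s = numeric()),
                samples = data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                                     depth_m = numeric(), dive_id = integer()))
  if (length(ts) == 0) return(empty)
  run <- cumsum(c(TRUE, diff(as.numeric(ts)) > 2 * sample_s))
  max_by_run <- tapply(depth, run, max)
  keep_run <- as.integer(names(max_by_run))[max_by_run >= min_depth_m]
  if (length(keep_run) == 0) return(empty)
  sel <- run %in% keep_run
  run_sel <- run[sel]
  dive_id <- match(run_sel, keep_run)
  ts <- ts[sel]; depth <- depth[sel]
  start <- ts[!duplicated(dive_id)]
  end <- ts[!duplicated(dive_id, fromLast = TRUE)]
  dives <- data.frame(dive_id = seq_along(start), start = start, end = end,
                      max_depth_m = as.numeric(tapply(depth, dive_id, max)),
                      duration_s = as.numeric(difftime(end, start, units = "secs")) + sample_s)
  dives$pdi_s <- c(as.numeric(difftime(start[-1], end[-length(end)], units = "secs")),
                   NA_real_)
  list(dives = dives,
       samples = data.frame(timestamp = ts, depth_m = depth, dive_id = dive_id))
}

#' Per-dive metrics from the depth samples of one dive
#'
#' Vertical velocity between successive records is
#' `v_i = (depth_{i+1} - depth_i) / dt`. The bottom phase runs from the
#' first sample whose forward |v| is below 0.5 m/s to the last sample
#' whose backward |v| is below 0.5 m/s (absolute value: ascent
#' velocities are negative in this sign convention). Bottom time is that
#' span, 0 if no sample qualifies. Descent rate is max depth over the
#' time from dive start to the first bottom sample; ascent rate is max
#' depth over the time from the last bottom sample to dive end (to/from
#' the max-depth sample when the bottom phase is empty).
#'
#' @param times POSIXct or numeric seconds of the dive's samples.
#' @param depths depths (m), same length.
#' @param v_threshold_ms bottom-phase velocity threshold (0.5 m/s).
#' @return list: `bottom_time_s`, `descent_rate_ms`, `ascent_rate_ms`,
#'   `max_depth_m`.
#' @export
dive_metrics <- function(times, depths, v_threshold_ms = 0.5) {
  t <- as.numeric(times)
  n <- length(t)
  stopifnot(n >= 3, length(depths) == n)
  v <- diff(depths) / diff(t)
  low <- abs(v) < v_threshold_ms          # low[i]: forward velocity at sample i
  max_depth <- max(depths)
  i_max <- which.max(depths)
  if (any(low)) {
    i_first <- which(low)[1]              # first sample with low forward v
    i_last <- max(which(low)) + 1         # last sample with low backward v
    bottom <- t[i_last] - t[i_first]
    dt_desc <- t[i_first] - t[1]
    dt_asc <- t[n] - t[i_last]
  } else {
    bottom <- 0
    dt_desc <- t[i_max] - t[1]
    dt_asc <- t[n] - t[i_max]
  }
  half <- mean(diff(t)) / 2               # guard: max depth at an endpoint
  list(bottom_time_s = bottom,
       descent_rate_ms = max_depth / max(dt_desc, half),
       ascent_rate_ms = max_depth / max(dt_asc, half),
       max_depth_m = max_depth)
}

#' Fill metrics for all detected dives
#'
#' @param detected list from [detect_dives()].
#' @inheritParams dive_metrics
#' @return the `dives` data.frame with `bottom_time_s`,
#'   `descent_rate_ms`, `ascent_rate_ms` columns added.
#' @export
fill_dive_metrics <- function(detected, v_threshold_ms = 0.5) {
  dives <- detected$dives
  sp <- split(detected$samples, detected$samples$dive_id)
  m <- lapply(sp, function(s) {
    if (nrow(s) < 3)
      return(list(bottom_time_s = 0,
                  descent_rate_ms = max(s$depth_m) / 4,
                  ascent_rate_ms = max(s$depth_m) / 4))
    dive_metrics(s$timestamp, s$depth_m, v_threshold_ms)
  })
  dives$bottom_time_s <- vapply(m, `[[`, numeric(1), "bottom_time_s")[as.character(dives$dive_id)]
  dives$descent_rate_ms <- vapply(m, `[[`, numeric(1), "descent_rate_ms")[as.character(dives$dive_id)]
  dives$ascent_rate_ms <- vapply(m, `[[`, numeric(1), "ascent_rate_ms")[as.character(dives$dive_id)]
  dives
}

## negative log-likelihood of the two-process exponential mixture
## f(t) = p lf exp(-lf t) + (1-p) ls exp(-ls t), parameterised to
## enforce 0 < p < 1 and lf > ls > 0
mixture_nll <- function(theta, t) {
  p <- stats::plogis(theta[1])
  ls <- exp(theta[2])
  lf <- ls + exp(theta[3])
  d <- p * lf * exp(-lf * t) + (1 - p) * ls * exp(-ls * t)
  -sum(log(pmax(d, 1e-300)))
}

#' Maximum-likelihood bout-ending criterion from post-dive intervals
#'
#' Fits the two-process exponential mixture
#' `f(t) = p lf exp(-lf t) + (1 - p) ls exp(-ls t)` to the PDIs (fast
#' process: within-bout pauses; slow process: between-bout gaps) by
#' maximum likelihood with a deterministic multi-start over
#' quantile-derived initial values. The bout-ending criterion (BEC) is
#' the intersection of the two weighted densities,
#' `t* = log(p lf / ((1 - p) ls)) / (lf - ls)`.
#'
#' A fit is declared single-process (error of class
#' `murrelog_single_process`) when the rate ratio collapses
#' (`lf/ls < 1.5`), the weight hits a boundary, or the mixture does not
#' improve on a single exponential by a likelihood-ratio margin.
#'
#' @param pdis post-dive intervals in seconds (NA dropped); at least 50.
#' @return object of class `bout_model`: `p_fast`, `lambda_fast`,
#'   `lambda_slow`, `bec_s`, `n_intervals`, `loglik`.
#' @export
fit_bout_criterion <- function(pdis) {
  t <- pdis[is.finite(pdis)]
  if (length(t) < 50)
    stop("fit_bout_criterion: need at least 50 finite post-dive intervals", call. = FALSE)
  q <- stats::quantile(t, c(0.25, 0.5, 0.75, 0.9))
  starts <- list()
  for (p0 in c(0.3, 0.5, 0.7, 0.9))
    for (r in list(c(1 / q[[1]], 1 / q[[4]]), c(1 / q[[2]], 1 / max(t) * 2))) {
      ls0 <- min(r); lf0 <- max(r) * 2
      if (lf0 <= ls0) lf0 <- ls0 * 5
      starts[[length(starts) + 1]] <-
        c(stats::qlogis(p0), log(ls0), log(lf0 - ls0))
    }
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(stats::optim(th0, mixture_nll, t = t, method = "Nelder-Mead",
                                 control = list(maxit = 2000, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("fit_bout_criterion: optimization failed", call. = FALSE)
  p <- stats::plogis(best$par[1])
  ls <- exp(best$par[2])
  lf <- ls + exp(best$par[3])
  ll <- -best$value
  ll_single <- length(t) * log(1 / mean(t)) - length(t)
  if (lf / ls < 1.5 || p < 0.005 || p > 0.995 || 2 * (ll - ll_single) < 12)
    stop(structure(class = c("murrelog_single_process", "error", "condition"),
                   list(message = "fit_bout_criterion: degenerate fit, intervals consistent with a single exponential process",
                        call = NULL)))
  bec <- log(p * lf / ((1 - p) * ls)) / (lf - ls)
  structure(list(p_fast = p, lambda_fast = lf, lambda_slow = ls,
                 bec_s = bec, n_intervals = length(t), loglik = ll),
            class = "bout_model")
}

#' @export
print.bout_model <- function(x, ...) {
  cat(sprintf("Exponential-mixture bout model (n = %d PDIs)\n", x$n_intervals))
  cat(sprintf("  p_fast = %.3f, lambda_fast = %.5f /s, lambda_slow = %.5f /s\n",
              x$p_fast, x$lambda_fast, x$lambda_slow))
  cat(sprintf("  bout-ending criterion = %.1f s, loglik = %.2f\n", x$bec_s, x$loglik))
  invisible(x)
}

#' Closed-form BEC for known mixture parameters
#' @param p mixture weight of the fast process.
#' @param lambda_fast,lambda_slow rates (1/s), fast > slow.
#' @return density-intersection time in seconds.
#' @export
bec_closed_form <- function(p, lambda_fast, lambda_slow)
  log(p * lambda_fast / ((1 - p) * lambda_slow)) / (lambda_fast - lambda_slow)

#' Assign dives to bouts given a bout-ending criterion
#'
#' The first dive opens bout 1; every PDI above `bec_s` ends the bout
#' and the following dive opens a new one. Bout ids are contiguous.
#'
#' @param dives data.frame with a `pdi_s` column, time-sorted.
#' @param bec_s bout-ending criterion in seconds.
#' @return `dives` with a `bout_id` column.
#' @export
assign_bouts <- function(dives, bec_s) {
  stopifnot(bec_s > 0)
  n <- nrow(dives)
  if (n == 0) { dives$bout_id <- integer(); return(dives) }
  brk <- c(FALSE, (dives$pdi_s > bec_s)[-n])
  brk[is.na(brk)] <- FALSE
  dives$bout_id <- as.integer(1 + cumsum(brk))
  dives
}

#' Linear dive-duration-on-depth model
#'
#' Dive duration and depth are very highly correlated in murres, so a
#' simple linear fit supplies the expected duration for a dive of a
#' given depth, the baseline against which bottom time is scored.
#'
#' @param dives data.frame with `duration_s` and `max_depth_m`.
#' @return an `lm` object.
#' @export
fit_duration_depth <- function(dives)
  stats::lm(duration_s ~ max_depth_m, data = dives)

#' Index of patch quality (IPQ)
#'
#' Per-dive IPQ increases with bottom time at a given depth: by default
#' `ipq = bottom_time / Dhat(depth)` where `Dhat` is the dataset's
#' fitted duration-on-depth prediction (see [fit_duration_depth()]).
#' Surface pauses outside foraging bouts are excluded by scoring only
#' dives in bouts with at least `min_bout_dives` dives, and summarising
#' as mean IPQ per bout. The scoring function is pluggable.
#'
#' @param dives data.frame with `bout_id`, `bottom_time_s`,
#'   `max_depth_m`.
#' @param model fitted duration-depth model; an unfitted/missing model
#'   is an error.
#' @param ipq_fun function(bottom_time_s, depth_m, dhat_s) -> score.
#' @param min_bout_dives minimum dives for a bout to count as foraging.
#' @return list: `dives` (with `ipq` column, NA outside foraging bouts)
#'   and `bouts` (bout_id, n_dives, mean_ipq).
#' @export
compute_ipq <- function(dives, model,
                        ipq_fun = function(bt, depth, dhat) bt / dhat,
                        min_bout_dives = 2) {
  if (missing(model) || !inherits(model, "lm"))
    stop("compute_ipq: a fitted duration-depth model is required", call. = FALSE)
  if (is.null(dives$bout_id))
    stop("compute_ipq: dives must carry bout_id (run assign_bouts first)", call. = FALSE)
  dhat <- as.numeric(stats::predict(model, newdata = dives))
  if (any(dhat <= 0))
    stop("compute_ipq: non-positive predicted duration", call. = FALSE)
  bout_n <- table(dives$bout_id)
  in_forage <- bout_n[as.character(dives$bout_id)] >= min_bout_dives
  dives$ipq <- ifelse(in_forage, ipq_fun(dives$bottom_time_s, dives$max_depth_m, dhat),
                      NA_real_)
  scored <- dives[!is.na(dives$ipq), , drop = FALSE]
  bouts <- aggregate(ipq ~ bout_id, data = scored, FUN = mean)
  names(bouts)[2] <- "mean_ipq"
  bouts$n_dives <- as.integer(bout_n[as.character(bouts$bout_id)])
  list(dives = dives, bouts = bouts[, c("bout_id", "n_dives", "mean_ipq")])
}

#' Accumulated dive time per UTC day
#'
#' Sums dive durations per calendar day, splitting dives that span
#' midnight proportionally. Days inside the covered span with no dives
#' are reported as 0 minutes.
#'
#' @param dives data.frame with `start` (POSIXct) and `duration_s`.
#' @param span optional Date vector `c(first, last)` to report; defaults
#'   to the span covered by the dives.
#' @return data.frame (date, dive_min).
#' @export
daily_effort <- function(dives, span = NULL) {
  if (nrow(dives) == 0) {
    if (is.null(span)) return(data.frame(date = as.Date(character()), dive_min = numeric()))
    days <- seq(as.Date(span[1]), as.Date(span[2]), by = "day")
    return(data.frame(date = days, dive_min = 0))
  }
  s <- as.numeric(as.POSIXct(dives$start, tz = "UTC"))
  e <- s + dives$duration_s
  days <- seq(as.Date(as.POSIXct(min(s), origin = "1970-01-01", tz = "UTC")),
              as.Date(as.POSIXct(max(e), origin = "1970-01-01", tz = "UTC")), by = "day")
  if (!is.null(span))
    days <- seq(min(as.Date(span[1]), days[1]), max(as.Date(span[2]), days[length(days)]),
                by = "day")
  d0 <- as.numeric(as.POSIXct(paste(days, "00:00:00"), tz = "UTC"))
  mins <- vapply(seq_along(days), function(k) {
    lo <- d0[k]; hi <- lo + 86400
    sum(pmax(0, pmin(e, hi) - pmax(s, lo))) / 60
  }, numeric(1))
  data.frame(date = days, dive_min = mins)
}

#' Diel attribution of dives
#'
#' Assigns each dive the diel phase (day / twilight / night) of its
#' start instant at that date's position, taken as the nearest retained
#' daily fix within `max_match_days`; dives with no position near enough
#' are flagged unassigned. Returns per-day counts and percentages by
#' phase (percentages sum to 100 per day).
#'
#' @param dives data.frame with `start`.
#' @param positions data.frame with `date`, `lat`, `lon` (retained fixes).
#' @param config a [solar_config()].
#' @param max_match_days maximum date distance for a position match (3).
#' @return list: `dives` (with `diel_phase` column, NA when unassigned)
#'   and `daily` (date, n_day, n_twilight, n_night, pct_day,
#'   pct_twilight, pct_night).
#' @export
diel_dive_summary <- function(dives, positions, config = solar_config(),
                              max_match_days = 3) {
  pos_date <- as.Date(positions$date)
  dive_date <- as.Date(dives$start, tz = "UTC")
  idx <- vapply(seq_len(nrow(dives)), function(i) {
    d <- abs(as.numeric(pos_date - dive_date[i]))
    j <- which.min(d)
    if (length(j) == 0 || d[j] > max_match_days) NA_integer_ else j
  }, integer(1))
  phase <- rep(NA_character_, nrow(dives))
  ok <- !is.na(idx)
  if (any(ok))
    phase[ok] <- vapply(which(ok), function(i)
      diel_phase(dives$start[i], positions$lat[idx[i]], positions$lon[idx[i]], config),
      character(1))
  dives$diel_phase <- phase
  assigned <- dives[ok, , drop = FALSE]
  if (nrow(assigned) == 0)
    return(list(dives = dives, daily = data.frame()))
  tab <- table(as.Date(assigned$start, tz = "UTC"),
               factor(assigned$diel_phase, levels = c("day", "twilight", "night")))
  daily <- data.frame(date = as.Date(rownames(tab)),
                      n_day = as.integer(tab[, "day"]),
                      n_twilight = as.integer(tab[, "twilight"]),
                      n_night = as.integer(tab[, "night"]))
  tot <- daily$n_day + daily$n_twilight + daily$n_night
  daily$pct_day <- 100 * daily$n_day / tot
  daily$pct_twilight <- 100 * daily$n_twilight / tot
  daily$pct_night <- 100 * daily$n_night / tot
  list(dives = dives, daily = daily)
}
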