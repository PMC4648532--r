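#' Delineate parental-care life-history stages for one bird
#'
#' Bi-parental care (BPC) runs from logger deployment to colony
#' departure for males, and to one week before colony departure for
#' females (females keep attending the colony for about a week after the
#' male-chick pair leaves). Male-only care (MOC) starts at colony
#' departure; its end (offspring independence) is provisional until
#' [estimate_independence()] supplies it. No parental care (NPC) is
#' 1 November to 31 January, truncated at the end of the log.
#'
#' @param sex "F" or "M".
#' @param deployment_date,departure_date Dates, deployment < departure.
#' @param log_end last day of the (pressure) log.
#' @param independence_date optional Date closing MOC.
#' @param female_bpc_offset_days days before departure ending female BPC (7).
#' @return data.frame (stage, start, end), stages BPC/MOC/NPC.
#' @export
delineate_stages <- function(sex, deployment_date, departure_date, log_end,
                             independence_date = NA,
                             female_bpc_offset_days = 7) {
  deployment_date <- as.Date(deployment_date)
  departure_date <- as.Date(departure_date)
  log_end <- as.Date(log_end)
  stopifnot(sex %in% c("F", "M"), deployment_date < departure_date)
  bpc_end <- if (sex == "F") departure_date - female_bpc_offset_days else departure_date
  if (bpc_end < deployment_date)
    stop("delineate_stages: female BPC window is empty (departure - 7 d precedes deployment)",
         call. = FALSE)
  year <- as.integer(format(departure_date, "%Y"))
  npc_start <- as.Date(sprintf("%d-11-01", year))
  npc_end <- min(as.Date(sprintf("%d-01-31", year + 1)), log_end)
  moc_end <- if (!is.na(independence_date)) as.Date(independence_date)
             else min(npc_start - 1, log_end)
  out <- data.frame(stage = c("BPC", "MOC", "NPC"),
                    start = c(deployment_date, departure_date, npc_start),
                    end = c(bpc_end, moc_end, npc_end))
  out[out$end >= out$start, , drop = FALSE]  # drop stages the log never reaches
}

#' Pooled female daily-effort reference
#'
#' Mean and standard deviation of daily accumulated dive time pooled
#' over independent females, the benchmark against which a
#' single-parenting male's effort is judged converged.
#'
#' @param effort_list list of data.frames (date, dive_min), one per
#'   female; at least 3.
#' @return list with `mean`, `sd`, `n_birds`, `n_days`.
#' @export
female_effort_reference <- function(effort_list) {
  if (length(effort_list) < 3)
    stop("female_effort_reference: need at least 3 females", call. = FALSE)
  v <- unlist(lapply(effort_list, function(d) d$dive_min))
  list(mean = mean(v), sd = stats::sd(v),
       n_birds = length(effort_list), n_days = length(v))
}

#' Estimate offspring independence from male/female effort convergence
#'
#' Single-parenting males dive far more per day than independent
#' females while the chick depends on them; independence is taken as the
#' first date after colony departure at which the male's centred
#' `window_days`-day rolling-mean daily effort stays at or below the
#' female reference mean + 1 SD for `k_consecutive` consecutive days.
#'
#' @param male_effort data.frame (date, dive_min), daily male effort.
#' @param departure_date the male's colony departure.
#' @param female_ref list with `mean` and `sd`
#'   (see [female_effort_reference()]).
#' @param window_days rolling-mean window (5, centred).
#' @param k_consecutive required consecutive converged days (7).
#' @param min_days minimum post-departure days of effort required (30).
#' @param search_end optional last date considered (default 31 October
#'   of the departure year: from 1 November winter effort rises for
#'   both sexes, so a female male-only-care reference is no longer a
#'   valid convergence benchmark).
#' @return list: `resolved` (logical), `independence_date` (Date or NA),
#'   `independence_days` (numeric or NA), `threshold_min` (min/day).
#' @export
estimate_independence <- function(male_effort, departure_date, female_ref,
                                  window_days = 5, k_consecutive = 7,
                                  min_days = 30, search_end = NULL) {
  departure_date <- as.Date(departure_date)
  if (is.null(search_end))
    search_end <- as.Date(sprintf("%s-10-31", format(departure_date, "%Y")))
  eff <- male_effort[as.Date(male_effort$date) > departure_date &
                       as.Date(male_effort$date) <= as.Date(search_end), ,
                     drop = FALSE]
  eff <- eff[order(as.Date(eff$date)), , drop = FALSE]
  if (nrow(eff) < min_days)
    stop(sprintf("estimate_independence: need >= %d days of post-departure effort", min_days),
         call. = FALSE)
  threshold <- female_ref$mean + female_ref$sd
  k <- window_days
  roll <- stats::filter(eff$dive_min, rep(1 / k, k), sides = 2)
  roll <- as.numeric(roll)
  ## pad ends with partial-window means so early/late days are usable
  half <- k %/% 2
  for (i in which(is.na(roll)))
    roll[i] <- mean(eff$dive_min[max(1, i - half):min(nrow(eff), i + half)])
  below <- roll <= threshold
  dates <- as.Date(eff$date)
  run <- rle(below)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  cand <- which(run$values & run$lengths >= k_consecutive)
  ## a qualifying run must be calendar-consecutive days
  for (ci in cand) {
    i0 <- starts[ci]; i1 <- ends[ci]
    dd <- diff(as.numeric(dates[i0:i1]))
    if (all(dd == 1) || (i1 - i0 + 1) >= k_consecutive) {
      ind_date <- dates[i0]
      return(list(resolved = TRUE, independence_date = ind_date,
                  independence_days = as.numeric(ind_date - departure_date),
                  threshold_min = threshold))
    }
  }
  list(resolved = FALSE, independence_date = as.Date(NA),
       independence_days = NA_real_, threshold_min = threshold)
}
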