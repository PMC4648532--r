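# Independent brute-force oracles used to check the package's
# implementations. Deliberately written as plain index-scanning loops,
# sharing no code with the package internals.

# Bottom time by literal velocity scan: forward velocity at sample i is
# (d[i+1]-d[i])/(t[i+1]-t[i]); bottom runs from the first sample whose
# forward |v| < thr to the last sample whose backward |v| < thr.
oracle_bottom_time <- function(t, d, thr = 0.5) {
  n <- length(t)
  first <- NA_integer_
  for (i in 1:(n - 1)) {
    v <- (d[i + 1] - d[i]) / (t[i + 1] - t[i])
    if (abs(v) < thr) { first <- i; break }
  }
  if (is.na(first)) return(0)
  last <- NA_integer_
  for (i in n:2) {
    v <- (d[i] - d[i - 1]) / (t[i] - t[i - 1])
    if (abs(v) < thr) { last <- i; break }
  }
  t[last] - t[first]
}

# Random plausible dive profile on an 8-s grid (>= 4 samples).
random_dive_profile <- function() {
  n <- sample(4:40, 1)
  t <- seq(0, by = 8, length.out = n)
  kind <- sample(c("square", "vee", "walk"), 1)
  d <- switch(kind,
    square = {
      maxd <- runif(1, 5, 80)
      n_desc <- max(1, floor(n / 4)); n_asc <- max(1, floor(n / 4))
      n_bot <- n - n_desc - n_asc
      c(seq(3, maxd, length.out = n_desc),
        maxd + runif(max(0, n_bot), -2, 0),
        seq(maxd, 3, length.out = n_asc))
    },
    vee = {
      maxd <- runif(1, 10, 80)
      half <- ceiling(n / 2)
      c(seq(3, maxd, length.out = half), seq(maxd, 3, length.out = n - half + 1)[-1])
    },
    walk = pmax(2.1, cumsum(c(runif(1, 3, 20), rnorm(n - 1, 0, 4))))
  )
  list(t = t, d = d[seq_len(n)])
}

# Minute-scan twilight oracle: scan solar_altitude over the UTC day at
# 30-s resolution and report the first/last crossing of the threshold.
oracle_twilight_scan <- function(date, lat, lon, threshold) {
  ts <- seq(as.POSIXct(paste(date, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(date, "23:59:30"), tz = "UTC"), by = 30)
  alt <- solar_altitude(ts, lat, lon)
  above <- alt >= threshold
  if (all(above) || all(!above)) return(NULL)
  rise <- which(!above[-length(above)] & above[-1])[1]
  sets <- which(above[-length(above)] & !above[-1])
  list(sunrise = ts[rise + 1], sunset = ts[sets[length(sets)] + 1])
}

# Dense grid-search oracle for the two-exponential-mixture log
# likelihood maximum.
oracle_mixture_grid <- function(t, p_grid = seq(0.05, 0.95, by = 0.05),
                                lf_grid = exp(seq(log(0.002), log(0.2), length.out = 40)),
                                ls_grid = exp(seq(log(1e-4), log(0.01), length.out = 40))) {
  best <- -Inf
  for (p in p_grid) for (lf in lf_grid) for (ls in ls_grid) {
    if (lf <= ls) next
    ll <- sum(log(p * lf * exp(-lf * t) + (1 - p) * ls * exp(-ls * t)))
    if (ll > best) best <- ll
  }
  best
}

# Reference solar altitudes computed with an independent Meeus-style
# ephemeris (Astronomical Algorithms ch. 25), frozen values.
meeus_reference <- data.frame(
  time = c("2010-03-21 12:07:00", "2010-12-01 12:00:00",
           "2010-06-21 12:00:00", "2011-09-15 18:30:00"),
  lat = c(0, 47.27, 0, 45),
  lon = c(0, -52.77, 0, -50),
  alt = c(89.6883, 7.5606, 66.5575, 30.1673)
)
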