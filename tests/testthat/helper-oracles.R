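# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force day loops for the accumulators and
# a Meeus-style solar-position calculation for daylength.

# day-by-day chilling count: [start, onset) with inclusive bounds
oracle_chilling <- function(dates, tmean, start, onset, t_low, t_high) {
  n <- 0L
  for (i in seq_along(dates)) {
    d <- dates[i]
    if (d >= start && d < onset && !is.na(tmean[i]) &&
        tmean[i] >= t_low && tmean[i] <= t_high) {
      n <- n + 1L
    }
  }
  n
}

# day-by-day forcing accumulation: [t0, onset), strict threshold
oracle_forcing <- function(dates, tmean, t0, onset,
                           amplitude = 28.4, slope = 0.185, midpoint = 18.4,
                           threshold = 5) {
  total <- 0
  for (i in seq_along(dates)) {
    d <- dates[i]
    if (d >= t0 && d < onset && tmean[i] > threshold) {
      total <- total + amplitude / (1 + exp(-slope * (tmean[i] - midpoint)))
    }
  }
  total
}

# day-by-day precipitation sums for the onset year
oracle_precip <- function(dates, prcp, onset) {
  year <- as.integer(format(onset, "%Y"))
  to_onset <- 0; annual <- 0
  for (i in seq_along(dates)) {
    if (as.integer(format(dates[i], "%Y")) == year) {
      annual <- annual + prcp[i]
      if (dates[i] < onset) to_onset <- to_onset + prcp[i]
    }
  }
  c(to_onset = to_onset, annual = annual)
}

# Meeus/NOAA-style solar declination from the Julian century, and daylength
# from the sunrise hour angle at zenith 90.833 degrees. Independent of the
# Spencer-series implementation in the package.
oracle_daylength <- function(lat, doy, year) {
  stopifnot(length(lat) == 1, length(doy) == 1)
  date <- as.Date(sprintf("%d-01-01", year)) + (doy - 1)
  jd <- as.numeric(date) + 2440587.5 + 0.5   # noon-ish Julian day
  jc <- (jd - 2451545) / 36525
  l0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  m <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  mr <- m * pi / 180
  eqc <- sin(mr) * (1.914602 - jc * (0.004817 + 1.4e-05 * jc)) +
    sin(2 * mr) * (0.019993 - 0.000101 * jc) + sin(3 * mr) * 0.000289
  true_long <- l0 + eqc
  app_long <- true_long - 0.00569 -
    0.00478 * sin((125.04 - 1934.136 * jc) * pi / 180)
  e0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  obliq <- e0 + 0.00256 * cos((125.04 - 1934.136 * jc) * pi / 180)
  decl <- asin(sin(obliq * pi / 180) * sin(app_long * pi / 180))
  phi <- lat * pi / 180
  cos_ha <- (cos(90.833 * pi / 180) - sin(phi) * sin(decl)) /
    (cos(phi) * cos(decl))
  cos_ha <- min(1, max(-1, cos_ha))
  2 * acos(cos_ha) * 180 / pi / 15
}

# small synthetic climate helper: constant or supplied daily values over
# given dates
toy_series <- function(dates, tmean, prcp = 0) {
  climate_series(data.frame(date = dates,
                            tmean_c = rep_len(tmean, length(dates)),
                            prcp_mm = rep_len(prcp, length(dates))))
}

# full-year (plus previous Nov-Dec) series with a seasonal cycle, for
# driver-table tests
toy_year_series <- function(year, mat = 8, amp = 10, seed = 1) {
  set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-11-01", year - 1)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  doy <- as.integer(format(dates, "%j"))
  tm <- mat + amp * cos(2 * pi * (doy - 200) / 365.25) + rnorm(length(dates))
  climate_series(data.frame(date = dates, tmean_c = tm,
                            prcp_mm = rbinom(length(dates), 1, 0.3) * 4))
}
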