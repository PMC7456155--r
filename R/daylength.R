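#' Daylength (photoperiod) from solar geometry
#'
#' Hours between sunrise and sunset for a latitude and day of year, using the
#' Spencer Fourier series for solar declination and the sunrise hour-angle
#' equation with the conventional refraction-adjusted solar zenith of
#' 90.833 degrees. Above the polar circles the hour-angle cosine is clamped,
#' giving 24 h for polar day and 0 h for polar night.
#'
#' @param latitude Latitude in decimal degrees north (-90 to 90). Recycled
#'   against `doy`.
#' @param doy Day of year, 1-based (Jan 1 = 1); must not exceed the number of
#'   days in `year`.
#' @param year Calendar year; only used for the length of the year (leap
#'   years have 366 days).
#' @return Numeric vector of daylengths in hours, in `[0, 24]`.
#' @examples
#' compute_daylength(45, 172, 2010)   # mid-latitude summer solstice
#' compute_daylength(70, 355, 2010)   # polar night -> 0
#' @export
compute_daylength <- function(latitude, doy, year = 2000L) {
  if (!is.numeric(latitude) || anyNA(latitude) ||
      any(latitude < -90) || any(latitude > 90)) {
    stop_arg("latitude must be in [-90, 90]")
  }
  ndays <- ifelse(is_leap_year(year), 366L, 365L)
  if (!is.numeric(doy) || anyNA(doy) || any(doy < 1) || any(doy > ndays)) {
    stop_arg("doy must be in [1, days-in-year]")
  }
  n <- max(length(latitude), length(doy), length(year))
  latitude <- rep_len(latitude, n)
  doy <- rep_len(doy, n)
  ndays <- rep_len(ndays, n)

  # Spencer (1971) series: declination from the fractional year angle.
  g <- 2 * pi * (doy - 1) / ndays
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)

  phi <- latitude * pi / 180
  zenith <- 90.833 * pi / 180
  cos_omega <- (cos(zenith) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  cos_omega <- pmin(1, pmax(-1, cos_omega))
  omega_deg <- acos(cos_omega) * 180 / pi
  2 * omega_deg / 15
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

days_in_year <- function(year) ifelse(is_leap_year(year), 366L, 365L)

#' Convert a year and day-of-year to a calendar date
#'
#' @param year Calendar year.
#' @param doy 1-based day of year.
#' @return A `Date`.
#' @export
doy_to_date <- function(year, doy) {
  nd <- days_in_year(year)
  if (anyNA(doy) || any(doy < 1) || any(doy > nd)) {
    stop_arg("doy must be in [1, ", max(nd), "] for the given year(s)")
  }
  as.Date(paste0(year, "-01-01")) + (doy - 1)
}
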