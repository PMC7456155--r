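#' Parameters of the sigmoid forcing-unit response
#'
#' Daily forcing units accumulate as a sigmoid function of the daily mean
#' temperature, `DFU(T) = amplitude / (1 + exp(-slope * (T - midpoint)))`,
#' on days with `T > t_threshold`, from `t0` (default Jan 1 of the onset
#' year) up to, but excluding, the onset day.
#'
#' @param amplitude Saturation level of the daily response, forcing units
#'   per day (default 28.4).
#' @param slope Steepness of the sigmoid, 1/degree C (default 0.185).
#' @param midpoint Temperature of the half-maximum response, degrees C
#'   (default 18.4).
#' @param t_threshold Strict lower temperature threshold for any
#'   accumulation, degrees C (default 5; a day at exactly 5 contributes 0).
#' @return A `forcing_params` list.
#' @export
forcing_params <- function(amplitude = 28.4, slope = 0.185, midpoint = 18.4,
                           t_threshold = 5) {
  if (amplitude <= 0) stop_arg("amplitude must be > 0")
  if (slope <= 0) stop_arg("slope must be > 0")
  structure(list(amplitude = amplitude, slope = slope, midpoint = midpoint,
                 t_threshold = t_threshold),
            class = "forcing_params")
}

#' Daily forcing units for a vector of temperatures
#'
#' @param tmean Daily mean temperatures, degrees C.
#' @param params A [forcing_params()].
#' @return Forcing units per day; 0 at or below the threshold.
#' @export
forcing_daily <- function(tmean, params = forcing_params()) {
  dfu <- params$amplitude /
    (1 + exp(-params$slope * (tmean - params$midpoint)))
  ifelse(tmean > params$t_threshold, dfu, 0)
}

#' Definition of a chilling window
#'
#' Chilling days are days whose daily mean temperature lies inside
#' `[t_low, t_high]` (both bounds inclusive), counted from `start_month`/
#' `start_day` of the year preceding onset up to, but excluding, the onset
#' day. The default window is -5 to 5 degrees C from Nov 1; alternative
#' windows `[0, 5]`, `[-5, 0]` and `[-10, 0]` are used for threshold
#' comparison.
#'
#' @param t_low,t_high Window bounds in degrees C, `t_low < t_high`.
#' @param start_month,start_day Calendar start of accumulation in the year
#'   before onset (default Nov 1).
#' @return A `chilling_window` list.
#' @export
chilling_window <- function(t_low = -5, t_high = 5,
                            start_month = 11L, start_day = 1L) {
  if (!(t_low < t_high)) stop_arg("t_low must be < t_high")
  structure(list(t_low = t_low, t_high = t_high,
                 start_month = as.integer(start_month),
                 start_day = as.integer(start_day)),
            class = "chilling_window")
}

chilling_start_date <- function(window, onset_year) {
  as.Date(sprintf("%d-%02d-%02d", onset_year - 1L,
                  window$start_month, window$start_day))
}

#' Mean annual temperature of a site-year
#'
#' Arithmetic mean of the daily mean temperature over Jan 1 to Dec 31 of
#' `year`, under the package gap policy (see [climate_window()]).
#'
#' @param series A [climate_series()].
#' @param year Calendar year.
#' @return Mean annual temperature, degrees C.
#' @export
compute_mat <- function(series, year) {
  w <- climate_window(series, as.Date(sprintf("%d-01-01", year)),
                      as.Date(sprintf("%d-12-31", year)))
  mean(w$tmean_c)
}

#' Chilling days before onset
#'
#' Number of days with daily mean temperature inside the chilling window
#' (inclusive bounds), over `[window start, onset_date)`; the onset day
#' itself is excluded.
#'
#' @param series A [climate_series()].
#' @param onset_date Onset `Date`.
#' @param window A [chilling_window()].
#' @return Integer count of chilling days.
#' @export
compute_chilling <- function(series, onset_date, window = chilling_window()) {
  onset_date <- as.Date(onset_date)
  start <- chilling_start_date(window, as.integer(format(onset_date, "%Y")))
  if (onset_date < start) stop_arg("onset_date precedes the chilling window start")
  if (onset_date == start) return(0L)
  w <- climate_window(series, start, onset_date - 1)
  sum(w$tmean_c >= window$t_low & w$tmean_c <= window$t_high)
}

#' Accumulated forcing units before onset
#'
#' Sum of daily forcing units ([forcing_daily()]) over `[t0, onset_date)`;
#' the onset day itself is excluded.
#'
#' @param series A [climate_series()].
#' @param onset_date Onset `Date`.
#' @param params A [forcing_params()].
#' @param t0 Start of accumulation; default Jan 1 of the onset year.
#' @return Accumulated forcing units (non-negative).
#' @export
compute_forcing <- function(series, onset_date, params = forcing_params(),
                            t0 = NULL) {
  onset_date <- as.Date(onset_date)
  if (is.null(t0)) {
    t0 <- as.Date(sprintf("%s-01-01", format(onset_date, "%Y")))
  }
  t0 <- as.Date(t0)
  if (onset_date < t0) stop_arg("onset_date precedes forcing start t0")
  if (onset_date == t0) return(0)
  w <- climate_window(series, t0, onset_date - 1)
  sum(forcing_daily(w$tmean_c, params))
}

#' Drought index of the month before onset
#'
#' Looks up the monthly drought-index value (e.g. scPDSI) for the full
#' calendar month immediately preceding the onset month, with year rollover
#' for January onsets.
#'
#' @param index_table data.frame with columns `site_id`, `year`, `month`,
#'   `value`.
#' @param site_id Site identifier.
#' @param onset_date Onset `Date`.
#' @return The monthly index value.
#' @export
compute_moisture <- function(index_table, site_id, onset_date) {
  onset_date <- as.Date(onset_date)
  m <- as.integer(format(onset_date, "%m")) - 1L
  y <- as.integer(format(onset_date, "%Y"))
  if (m == 0L) { m <- 12L; y <- y - 1L }
  hit <- index_table$site_id == site_id &
    index_table$year == y & index_table$month == m
  if (sum(hit) != 1L) {
    stop_data(sprintf("drought index missing for site %s, %d-%02d",
                      site_id, y, m))
  }
  index_table$value[hit]
}

#' Precipitation sums for the onset year
#'
#' Total precipitation over `[Jan 1, onset_date)` (onset day excluded) and
#' over the full onset calendar year.
#'
#' @param series A [climate_series()].
#' @param onset_date Onset `Date`.
#' @return Named numeric vector `c(precip_to_onset=, precip_annual=)`, mm.
#' @export
compute_precip_sums <- function(series, onset_date) {
  onset_date <- as.Date(onset_date)
  year <- as.integer(format(onset_date, "%Y"))
  w <- climate_window(series, as.Date(sprintf("%d-01-01", year)),
                      as.Date(sprintf("%d-12-31", year)))
  to_onset <- sum(w$prcp_mm[w$date < onset_date])
  c(precip_to_onset = to_onset, precip_annual = sum(w$prcp_mm))
}

# Driver values for one site-year, indexed by candidate onset DOY D under
# the same conventions as the single-record functions: accumulations over
# [start, D) (onset day excluded), inclusive chilling bounds, strict
# forcing threshold. Shared by build_driver_table (for speed: one climate
# extraction per site-year instead of per record) and by the synthetic
# onset solver. The gap policy is applied once to the whole required span
# (Nov 1 of the previous year through Dec 31).
driver_grids <- function(series, lat, year, window = chilling_window(),
                         params = forcing_params()) {
  nd <- days_in_year(year)
  jan1 <- as.Date(sprintf("%d-01-01", year))
  chill_start <- chilling_start_date(window, year)
  w <- climate_window(series, chill_start,
                      as.Date(sprintf("%d-12-31", year)))
  in_year <- w$date >= jan1
  t_pre <- w$tmean_c[!in_year]
  t_year <- w$tmean_c[in_year]
  prcp_year <- w$prcp_mm[in_year]
  dfu <- forcing_daily(t_year, params)
  chill <- as.numeric(t_year >= window$t_low & t_year <= window$t_high)
  chill_pre <- sum(t_pre >= window$t_low & t_pre <= window$t_high)
  list(nd = nd,
       mat = mean(t_year),
       forcing = c(0, cumsum(dfu)[-nd]),
       chilling = chill_pre + c(0, cumsum(chill)[-nd]),
       photoperiod = compute_daylength(lat, seq_len(nd), year),
       precip_to_onset = c(0, cumsum(prcp_year)[-nd]),
       precip_annual = sum(prcp_year))
}

#' Assemble the driver table for a set of onset observations
#'
#' For every onset record, computes the full predictor set: photoperiod on
#' the onset day, mean annual temperature of the onset year, accumulated
#' forcing units, chilling days, the drought index of the month before
#' onset, and the two precipitation sums. Records whose climate coverage is
#' unsatisfiable under the gap policy are dropped and reported (attribute
#' `"drops"`, plus a message).
#'
#' @param onsets data.frame with columns `tree_id`, `species`, `site_id`,
#'   `year`, `onset_doy` (integer DOY).
#' @param climates Named list of [climate_series()], one per `site_id`.
#' @param index_table Monthly drought-index table (see [compute_moisture()]).
#' @param sites data.frame with `site_id`, `lat` (needed for photoperiod);
#'   extra columns such as `biome` are carried through.
#' @param species_table Optional data.frame with `species`, `successional`;
#'   carried through for subgroup fits.
#' @param params A [forcing_params()].
#' @param window A [chilling_window()].
#' @return data.frame: one row per retained onset record with identifier,
#'   onset and driver columns (`photoperiod`, `mat`, `forcing`, `chilling`,
#'   `scpdsi`, `precip_to_onset`, `precip_annual`). Attribute `"drops"` is a
#'   data.frame of dropped records and reasons.
#' @export
build_driver_table <- function(onsets, climates, index_table, sites,
                               species_table = NULL,
                               params = forcing_params(),
                               window = chilling_window()) {
  need <- c("tree_id", "species", "site_id", "year", "onset_doy")
  if (!is.data.frame(onsets) || nrow(onsets) == 0L) {
    stop_arg("onsets must be a non-empty data.frame")
  }
  if (!all(need %in% names(onsets))) {
    stop_arg("onsets needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("site_id", "lat") %in% names(sites))) {
    stop_arg("sites needs columns site_id, lat")
  }
  lat <- sites$lat[match(onsets$site_id, sites$site_id)]
  if (anyNA(lat)) stop_data("onset record refers to a site absent from `sites`")

  n <- nrow(onsets)
  out <- data.frame(onsets, photoperiod = NA_real_, mat = NA_real_,
                    forcing = NA_real_, chilling = NA_real_,
                    scpdsi = NA_real_, precip_to_onset = NA_real_,
                    precip_annual = NA_real_)
  out$lat <- lat
  drop_reason <- character(n)
  if (any(onsets$onset_doy < 1 | onsets$onset_doy > days_in_year(onsets$year))) {
    stop_data("onset_doy outside [1, days-in-year]")
  }
  # one climate extraction per site-year; records then index the grids
  grp <- split(seq_len(n), paste(onsets$site_id, onsets$year))
  for (idx in grp) {
    sid <- as.character(onsets$site_id[idx[1]])
    yr <- onsets$year[idx[1]]
    ser <- climates[[sid]]
    if (is.null(ser)) { drop_reason[idx] <- "no climate series"; next }
    g <- tryCatch(driver_grids(ser, lat[idx[1]], yr, window, params),
                  woodonset_data_error = function(e) conditionMessage(e),
                  woodonset_arg_error = function(e) conditionMessage(e))
    if (is.character(g)) { drop_reason[idx] <- g; next }
    for (i in idx) {
      d <- onsets$onset_doy[i]
      val <- tryCatch(
        compute_moisture(index_table, sid, doy_to_date(yr, d)),
        woodonset_data_error = function(e) conditionMessage(e))
      if (is.character(val)) { drop_reason[i] <- val; next }
      out$photoperiod[i] <- g$photoperiod[d]
      out$mat[i] <- g$mat
      out$forcing[i] <- g$forcing[d]
      out$chilling[i] <- g$chilling[d]
      out$scpdsi[i] <- val
      out$precip_to_onset[i] <- g$precip_to_onset[d]
      out$precip_annual[i] <- g$precip_annual
    }
  }
  keep <- drop_reason == ""
  drops <- data.frame(tree_id = onsets$tree_id[!keep],
                      site_id = onsets$site_id[!keep],
                      year = onsets$year[!keep],
                      reason = drop_reason[!keep])
  if (nrow(drops) > 0L) {
    message(sprintf("build_driver_table: dropped %d of %d record(s): %s",
                    nrow(drops), n,
                    paste(utils::head(unique(drops$reason), 3), collapse = "; ")))
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(species_table) &&
      all(c("species", "successional") %in% names(species_table))) {
    out$successional <-
      species_table$successional[match(out$species, species_table$species)]
  }
  if ("biome" %in% names(sites)) {
    out$biome <- sites$biome[match(out$site_id, sites$site_id)]
  }
  attr(out, "drops") <- drops
  out
}
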