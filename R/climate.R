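#' Construct and validate a daily climate series
#'
#' A daily climate series is a plain `data.frame` with columns `date`
#' (`Date`), `tmean_c` (daily mean air temperature, degrees C) and `prcp_mm`
#' (daily precipitation, mm, non-negative). Rows must be sorted by date with
#' no duplicates; days may be absent (gaps), which the window extractor
#' repairs or rejects under the gap policy (see [climate_window()]).
#'
#' @param df data.frame with columns `date`, `tmean_c`, `prcp_mm`.
#' @param site_id Optional site identifier stored as an attribute.
#' @return The validated data.frame with class `climate_series` prepended.
#' @export
climate_series <- function(df, site_id = NULL) {
  need <- c("date", "tmean_c", "prcp_mm")
  if (!is.data.frame(df) || !all(need %in% names(df))) {
    stop_arg("climate series needs columns: ", paste(need, collapse = ", "))
  }
  df <- df[need]
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop_data("climate series has unparseable dates")
  if (is.unsorted(df$date, strictly = TRUE)) {
    if (anyDuplicated(df$date)) stop_data("duplicated dates in climate series")
    df <- df[order(df$date), , drop = FALSE]
  }
  ok_t <- is.finite(df$tmean_c) | is.na(df$tmean_c)
  if (!all(ok_t)) stop_data("non-finite tmean_c in climate series")
  if (any(df$prcp_mm < 0, na.rm = TRUE)) stop_data("negative prcp_mm")
  if (!is.null(site_id)) attr(df, "site_id") <- site_id
  class(df) <- c("climate_series", class(df))
  df
}

#' Extract a contiguous daily window from a climate series
#'
#' Returns one row per calendar day in `[start, end]`. Gaps (absent days or
#' `NA` temperatures) of at most `max_gap` days in total are repaired:
#' `tmean_c` is interpolated linearly between the nearest observed days and
#' `prcp_mm` for filled days is set to 0 (interpolating daily precipitation
#' is unphysical). Larger gaps, or gaps touching the window edges with no
#' neighbouring observation, are a data error naming the missing span.
#'
#' @param series A [climate_series()] (or coercible data.frame).
#' @param start,end Dates, inclusive.
#' @param max_gap Maximum number of missing days tolerated per window.
#' @return data.frame with columns `date`, `tmean_c`, `prcp_mm`, one row per
#'   day, plus a logical `filled` column marking interpolated days.
#' @export
climate_window <- function(series, start, end, max_gap = 5L) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop_arg("window end precedes start")
  days <- seq(start, end, by = "day")
  idx <- match(days, series$date)
  tmean <- series$tmean_c[idx]
  prcp <- series$prcp_mm[idx]
  miss <- is.na(tmean)
  if (any(miss)) {
    n_miss <- sum(miss)
    if (n_miss > max_gap) {
      stop_data(sprintf(
        "climate window %s..%s is missing %d day(s) (policy allows %d), e.g. %s",
        format(start), format(end), n_miss, max_gap,
        format(days[miss][1])))
    }
    if (miss[1] || miss[length(miss)]) {
      # no observation outside the window is consulted; edge gaps cannot be
      # interpolated
      stop_data(sprintf(
        "climate window %s..%s has a gap at its edge; cannot interpolate",
        format(start), format(end)))
    }
    tmean[miss] <- stats::approx(which(!miss), tmean[!miss],
                                 xout = which(miss))$y
    prcp[miss] <- 0
  }
  prcp[is.na(prcp)] <- 0
  data.frame(date = days, tmean_c = tmean, prcp_mm = prcp, filled = miss)
}
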