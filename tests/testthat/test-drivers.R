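# Unit tests for the environmental-driver computations against brute-force
# oracles and the documented accumulation conventions.

test_that("forcing sigmoid: midpoint, threshold, saturation, monotonicity", {
  p <- forcing_params()
  expect_equal(forcing_daily(18.4, p), 14.2)
  expect_equal(forcing_daily(5, p), 0)      # threshold is strict
  expect_equal(forcing_daily(4, p), 0)
  expect_gt(forcing_daily(5 + 1e-9, p), 0)
  tt <- seq(5.01, 60, by = 0.05)
  dfu <- forcing_daily(tt, p)
  expect_true(all(diff(dfu) > 0))
  expect_true(all(dfu > 0 & dfu < p$amplitude))
  expect_equal(sum(forcing_daily(rep(100, 30), p)), 30 * 28.4,
               tolerance = 0.5 / 852)
})

test_that("chilling count matches the worked example and window variants", {
  # the accumulation window opens Nov 1 of the year BEFORE onset; embed a
  # 10-day toy segment at the start of the onset year, with out-of-range
  # temperatures (20 C) before it so only the toy days can count
  dates <- seq(as.Date("2005-11-01"), as.Date("2006-01-11"), by = "day")
  tm <- rep(20, length(dates))
  toy <- c(-6, -5, -4, 0, 5, 6, 5, -5, 10, 2)
  toy_idx <- match(seq(as.Date("2006-01-01"), by = "day", length.out = 10),
                   dates)
  tm[toy_idx] <- toy
  ser <- toy_series(dates, tm)
  onset <- as.Date("2006-01-11")
  w <- chilling_window(-5, 5)
  expect_identical(compute_chilling(ser, onset, w),
                   oracle_chilling(dates, tm, dates[1], onset, -5, 5))
  expect_identical(compute_chilling(ser, onset, w), 7L)
  w2 <- chilling_window(0, 5)
  expect_identical(compute_chilling(ser, onset, w2), 4L)
  expect_identical(compute_chilling(toy_series(dates, 20), onset, w), 0L)
  # insufficient window coverage is a data error naming the gap
  expect_error(compute_chilling(ser, as.Date("2005-12-15"), w),
               class = "woodonset_data_error")
})

test_that("accumulators equal brute-force loops on randomized series", {
  # property-based: 100 random toy series, fixed seed
  set.seed(1234)
  for (rep in 1:100) {
    year <- sample(2000:2015, 1)
    start <- as.Date(sprintf("%d-11-01", year - 1))
    dates <- seq(start, as.Date(sprintf("%d-12-31", year)), by = "day")
    tm <- round(runif(length(dates), -15, 25), 1)
    pr <- round(rbinom(length(dates), 1, 0.4) * rgamma(length(dates), 1, 0.2), 2)
    ser <- climate_series(data.frame(date = dates, tmean_c = tm, prcp_mm = pr))
    onset <- doy_to_date(year, sample.int(300, 1))
    wl <- sort(runif(2, -10, 8)); wl <- c(wl[1], wl[1] + max(diff(wl), 1))
    w <- chilling_window(wl[1], wl[2])
    expect_identical(compute_chilling(ser, onset, w),
                     oracle_chilling(dates, tm, start, onset, wl[1], wl[2]))
    expect_equal(compute_forcing(ser, onset),
                 oracle_forcing(dates, tm, as.Date(sprintf("%d-01-01", year)),
                                onset))
    ps <- compute_precip_sums(ser, onset)
    op <- oracle_precip(dates, pr, onset)
    expect_equal(unname(ps), unname(op))
  }
})

test_that("forcing and chilling are non-decreasing in onset date", {
  ser <- toy_year_series(2010, seed = 99)
  onsets <- doy_to_date(2010, seq(10, 300, by = 10))
  f <- vapply(onsets, function(d) compute_forcing(ser, d), numeric(1))
  c_ <- vapply(onsets, function(d)
    as.numeric(compute_chilling(ser, d)), numeric(1))
  expect_true(all(diff(f) >= 0))
  expect_true(all(diff(c_) >= 0))
})

test_that("mean annual temperature and the gap policy behave as documented", {
  dates <- seq(as.Date("2010-01-01"), as.Date("2010-12-31"), by = "day")
  expect_equal(compute_mat(toy_series(dates, 7), 2010), 7)
  alt <- (seq_along(dates) - 1) %% 2
  expect_equal(compute_mat(toy_series(dates, alt), 2010), 182 / 365)

  # <= 5 missing days are interpolated
  drop5 <- toy_series(dates[-(100:104)], 7)
  expect_equal(compute_mat(drop5, 2010), 7)
  # 40 consecutive missing days violate the policy
  drop40 <- toy_series(dates[-(100:139)], 7)
  expect_error(compute_mat(drop40, 2010), class = "woodonset_data_error")
  # gap at the window edge cannot be interpolated
  edge <- toy_series(dates[-(1:3)], 7)
  expect_error(compute_mat(edge, 2010), class = "woodonset_data_error")
})

test_that("precip sums follow the half-open convention", {
  dates <- seq(as.Date("2011-01-01"), as.Date("2011-12-31"), by = "day")
  ser <- toy_series(dates, 10, prcp = 1)
  expect_equal(unname(compute_precip_sums(ser, doy_to_date(2011, 100))),
               c(99, 365))
  expect_equal(unname(compute_precip_sums(ser, as.Date("2011-01-01"))),
               c(0, 365))
  expect_equal(unname(compute_precip_sums(toy_series(dates, 10, 0),
                                          doy_to_date(2011, 50))), c(0, 0))
})

test_that("moisture lookup uses the prior calendar month with rollover", {
  idx <- data.frame(site_id = "A", year = c(2005, 2005, 2004),
                    month = c(4, 5, 12), value = c(-1.3, 2, 0.7))
  expect_equal(compute_moisture(idx, "A", as.Date("2005-05-14")), -1.3)
  expect_equal(compute_moisture(idx, "A", as.Date("2005-01-10")), 0.7)
  expect_error(compute_moisture(idx, "A", as.Date("2005-03-10")),
               class = "woodonset_data_error")
  expect_error(compute_moisture(idx, "B", as.Date("2005-05-14")),
               class = "woodonset_data_error")
})

test_that("driver table composes the unit computations and logs drops", {
  ser <- toy_year_series(2010, mat = 6, amp = 9, seed = 5)
  sites <- data.frame(site_id = "S1", lat = 48, biome = "temperate")
  idx <- expand.grid(site_id = "S1", year = 2009:2010, month = 1:12)
  idx$value <- round(sin(seq_len(nrow(idx))), 2)
  onsets <- data.frame(tree_id = c("t1", "t2", "t3"),
                       species = "PCAB", site_id = "S1", year = 2010,
                       onset_doy = c(60, 130, 200))
  tab <- build_driver_table(onsets, list(S1 = ser), idx, sites)
  expect_equal(nrow(tab), 3)
  expect_false(anyNA(tab[c("photoperiod", "mat", "forcing", "chilling",
                           "scpdsi", "precip_to_onset", "precip_annual")]))
  for (i in 1:3) {
    d <- doy_to_date(2010, onsets$onset_doy[i])
    expect_equal(tab$chilling[i], as.numeric(compute_chilling(ser, d)))
    expect_equal(tab$forcing[i], compute_forcing(ser, d))
    expect_equal(tab$scpdsi[i], compute_moisture(idx, "S1", d))
    expect_equal(tab$photoperiod[i],
                 compute_daylength(48, onsets$onset_doy[i], 2010))
    expect_equal(tab$mat[i], compute_mat(ser, 2010))
  }

  # a record whose climate coverage is missing gets dropped with a reason
  onsets2 <- rbind(onsets,
                   data.frame(tree_id = "t4", species = "PCAB",
                              site_id = "S1", year = 2012, onset_doy = 100))
  tab2 <- suppressMessages(build_driver_table(onsets2, list(S1 = ser), idx,
                                              sites))
  expect_equal(nrow(tab2), 3)
  drops <- attr(tab2, "drops")
  expect_equal(nrow(drops), 1)
  expect_equal(drops$tree_id, "t4")
  expect_match(drops$reason, "missing")

  expect_error(build_driver_table(onsets[0, ], list(S1 = ser), idx, sites),
               class = "woodonset_arg_error")
})
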