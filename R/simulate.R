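#' Configuration of the synthetic study generator
#'
#' Describes a synthetic Northern Hemisphere xylogenesis study: sites on a
#' latitudinal gradient, conifer species with latitudinal niches, daily
#' climate per site, monthly drought-index series, and onset dates drawn
#' from a crossed random-intercept linear model whose predictors are the
#' environmental drivers themselves. Defaults reproduce the reference
#' design: 79 sites over 23-67.5 degrees N, 21 species, 826 trees, 2,030
#' tree-year records, with generative fixed effects
#' `onset = 124.6 - 5.92*MAT + 0.12*forcing + 0.23*chilling + 1.09*scPDSI`
#' and random-intercept SDs 7.53 d (site), 2.42 d (species), 5.85 d
#' (residual). `model = "model1"` switches the generative fixed effects to
#' the photoperiod parameterisation
#' `onset = -160.1 + 18.88*photoperiod + 0.05*forcing + 0.05*chilling +
#' 0.64*scPDSI` with SDs 24.84 / 3.75 / 4.62 d.
#'
#' Site mean temperatures are linear in latitude, calibrated so site MATs
#' span roughly -2 to 23 degrees C over the latitude range; the seasonal
#' amplitude grows with latitude; daily noise is AR(1).
#'
#' @param n_sites,n_species,n_trees,n_records Design sizes.
#' @param lat_range Latitude range, degrees N.
#' @param years Observation years (climate is generated from Nov 1 of the
#'   year before the first).
#' @param model `"model2"` (MAT parameterisation, default) or `"model1"`
#'   (photoperiod parameterisation).
#' @param alpha,betas,sd_site,sd_species,sd_resid Generative truth; `NULL`
#'   means the model's defaults above. `betas` must be named by predictor.
#' @param mat_intercept,mat_slope Site MAT vs latitude (degrees C,
#'   C/degree).
#' @param mat_site_sd Site-level MAT scatter around the gradient, C.
#' @param amp_min Minimum seasonal half-amplitude, C: the amplitude floor
#'   reached at the coldest sites.
#' @param amp_site_sd Site-level scatter of the seasonal amplitude around
#'   its climatological target, C (continentality: maritime vs continental
#'   sites at the same mean temperature differ in seasonality).
#' @param ar1,innov_sd Daily AR(1) coefficient and innovation SD, C.
#' @param year_anom_sd SD of the site-year temperature anomaly, C: a single
#'   normal draw added to all days of a calendar year, emulating
#'   interannual climate variability (warm vs cold winters), which gives
#'   chilling and forcing genuine year-to-year variation within a site.
#' @param wet_prob,prcp_shape,prcp_scale Wet-day probability and gamma
#'   parameters of wet-day precipitation, mm.
#' @param scpdsi_ar,scpdsi_innov_sd Monthly drought-index AR(1) parameters.
#' @param site_skew Concentration exponent of the record-allocation skew
#'   toward mid/high-latitude (temperate/boreal) sites: allocation weight
#'   is `(0.02 + exp(-(lat - 50)^2 / 200))^site_skew`. 0 = uniform; the
#'   default 1 gives roughly 1-3% of trees to subtropical sites, echoing
#'   the heavy mid/high-latitude sampling of real monitoring networks.
#' @param niche_sd SD (degrees latitude) of species' site affinity.
#' @param solve_tol Tolerance (days) of the implicit onset solver: a record
#'   whose best candidate day misses self-consistency by more than this is
#'   discarded. The default 8 is about one sampling interval of weekly
#'   field campaigns.
#' @param obs_error_days Half-width (days) of the discrete-uniform onset
#'   dating error added to each emitted record, emulating weekly
#'   microcore sampling (onset is only located between two consecutive
#'   visits); 0 disables it.
#' @param seed Root seed; all stages derive named substreams from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_sites = 79L, n_species = 21L, n_trees = 826L,
                             n_records = 2030L, lat_range = c(23, 67.5),
                             years = 1998:2016,
                             model = c("model2", "model1"),
                             alpha = NULL, betas = NULL, sd_site = NULL,
                             sd_species = NULL, sd_resid = NULL,
                             mat_intercept = 36.1, mat_slope = -0.573,
                             mat_site_sd = 1.0,
                             amp_min = 10, amp_site_sd = 1,
                             ar1 = 0.7, innov_sd = 1.5,
                             year_anom_sd = 2,
                             wet_prob = 0.35, prcp_shape = 0.7,
                             prcp_scale = 8,
                             scpdsi_ar = 0.9, scpdsi_innov_sd = 0.9,
                             site_skew = 1.5, niche_sd = 12,
                             solve_tol = 8, obs_error_days = 3L,
                             seed = 1L) {
  model <- match.arg(model)
  truth <- if (model == "model2") {
    list(alpha = 124.6,
         betas = c(mat = -5.92, forcing = 0.12, chilling = 0.23,
                   scpdsi = 1.09),
         sd_site = 7.53, sd_species = 2.42, sd_resid = 5.85)
  } else {
    list(alpha = -160.1,
         betas = c(photoperiod = 18.88, forcing = 0.05, chilling = 0.05,
                   scpdsi = 0.64),
         sd_site = 24.84, sd_species = 3.75, sd_resid = 4.62)
  }
  if (is.null(alpha)) alpha <- truth$alpha
  if (is.null(betas)) betas <- truth$betas
  if (is.null(sd_site)) sd_site <- truth$sd_site
  if (is.null(sd_species)) sd_species <- truth$sd_species
  if (is.null(sd_resid)) sd_resid <- truth$sd_resid
  if (is.null(names(betas)) || any(!nzchar(names(betas)))) {
    stop_arg("betas must be a named vector of predictor coefficients")
  }
  if (any(c(sd_site, sd_species, sd_resid) < 0)) stop_arg("sd_* must be >= 0")
  if (n_records < n_sites) stop_arg("n_records must be >= n_sites")
  if (n_sites < 2L) stop_arg("n_sites must be >= 2")
  cfg <- list(n_sites = as.integer(n_sites), n_species = as.integer(n_species),
              n_trees = as.integer(n_trees), n_records = as.integer(n_records),
              lat_range = lat_range, years = as.integer(years), model = model,
              alpha = alpha, betas = betas, sd_site = sd_site,
              sd_species = sd_species, sd_resid = sd_resid,
              mat_intercept = mat_intercept, mat_slope = mat_slope,
              mat_site_sd = mat_site_sd, amp_min = amp_min,
              amp_site_sd = amp_site_sd,
              ar1 = ar1, innov_sd = innov_sd,
              year_anom_sd = year_anom_sd,
              wet_prob = wet_prob, prcp_shape = prcp_shape,
              prcp_scale = prcp_scale, scpdsi_ar = scpdsi_ar,
              scpdsi_innov_sd = scpdsi_innov_sd, site_skew = site_skew,
              niche_sd = niche_sd, solve_tol = solve_tol,
              obs_error_days = as.integer(obs_error_days),
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

# named substreams off the root seed (kept < 2^31)
substream <- function(config, name) {
  offset <- c(sites = 101L, species = 102L, climate = 2000L,
              scpdsi = 3000L, effects = 104L)[[name]]
  (config$seed + offset) %% .Machine$integer.max
}

#' Generate the site table
#'
#' Latitudes are stratified-uniform over the configured range (one site per
#' stratum) so the gradient is covered evenly; elevation is uniform on
#' 0-3,000 m; biome follows latitude bands (>= 55 boreal, 40-55 temperate,
#' 30-40 mediterranean, < 30 subtropical). Each site also receives its true
#' long-term mean temperature (`mat_true`, linear in latitude plus scatter)
#' and seasonal half-amplitude (`amp`), which the climate generator uses.
#'
#' @param config A [generator_config()].
#' @return data.frame: `site_id`, `lat`, `lon`, `elev_m`, `biome`,
#'   `mat_true`, `amp`.
#' @export
generate_sites <- function(config) {
  n <- config$n_sites
  if (n < 2L) stop_arg("n_sites must be >= 2")
  set.seed(substream(config, "sites"))
  breaks <- seq(config$lat_range[1], config$lat_range[2], length.out = n + 1)
  lat <- stats::runif(n, breaks[-(n + 1)], breaks[-1])
  biome <- cut(lat, c(-Inf, 30, 40, 55, Inf),
               labels = c("subtropical", "mediterranean", "temperate",
                          "boreal"), right = FALSE)
  # clamped to the thermal range that supports the sampled conifer
  # forests (observed site MATs run from about -2.3 to 22.9 C)
  mat_true <- pmin(pmax(config$mat_intercept + config$mat_slope * lat +
                          stats::rnorm(n, 0, config$mat_site_sd),
                        -3.5), 23.5)
  # seasonal amplitude with an amplitude floor and a mild-winter cap:
  # winter means run from about -10 C at boreal sites through -2 C at
  # temperate sites to +6.5 C at the warmest subtropical sites, keeping
  # chilling counts moderate and the implicit onset equilibrium early and
  # well separated from midsummer
  amp <- pmax(config$amp_min, mat_true - 6.5) +
    stats::rnorm(n, 0, config$amp_site_sd)
  data.frame(
    site_id = sprintf("S%03d", seq_len(n)),
    lat = lat,
    lon = stats::runif(n, -125, 140),
    elev_m = stats::runif(n, 0, 3000),
    biome = as.character(biome),
    mat_true = mat_true,
    amp = amp
  )
}

#' Generate the species table
#'
#' Species are given a latitudinal niche centre (evenly spaced over the
#' site range with jitter) used to assign them to sites, and a successional
#' type (two-thirds early, one-third late, echoing the usual balance of
#' pioneer pines/larches vs. shade-tolerant firs/spruces).
#'
#' @param config A [generator_config()].
#' @return data.frame: `species`, `niche_lat`, `successional`.
#' @export
generate_species <- function(config) {
  n <- config$n_species
  set.seed(substream(config, "species"))
  niche <- seq(config$lat_range[1], config$lat_range[2], length.out = n) +
    stats::rnorm(n, 0, 2)
  n_early <- round(2 * n / 3)
  succ <- rep("late", n)
  succ[sample.int(n, n_early)] <- "early"
  data.frame(species = sprintf("SP%02d", seq_len(n)),
             niche_lat = pmin(pmax(niche, 15), 75),
             successional = succ)
}

#' Generate a daily climate series for one site
#'
#' `tmean(d) = mat_true + amp * cos(2*pi*(doy - 200)/365.25) + AR(1) noise`,
#' from Nov 1 of the year before the first requested year through Dec 31 of
#' the last. Precipitation is a wet/dry Bernoulli-gamma mixture.
#'
#' @param site One row of the [generate_sites()] table.
#' @param years Integer vector of observation years.
#' @param config A [generator_config()].
#' @param seed Seed for this site's series.
#' @return A [climate_series()].
#' @export
generate_climate <- function(site, years, config, seed) {
  set.seed(seed %% .Machine$integer.max)
  dates <- seq(as.Date(sprintf("%d-11-01", min(years) - 1L)),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  doy <- as.integer(format(dates, "%j"))
  n <- length(dates)
  yr <- as.integer(format(dates, "%Y"))
  yr_levels <- sort(unique(yr))
  anom <- stats::rnorm(length(yr_levels), 0, config$year_anom_sd)
  seasonal <- site$mat_true + site$amp * cos(2 * pi * (doy - 200) / 365.25) +
    anom[match(yr, yr_levels)]
  if (config$innov_sd > 0) {
    e0 <- stats::rnorm(1, 0, config$innov_sd / sqrt(1 - config$ar1^2))
    innov <- stats::rnorm(n, 0, config$innov_sd)
    noise <- as.numeric(stats::filter(innov, config$ar1, method = "recursive",
                                      init = e0))
  } else noise <- numeric(n)
  wet <- stats::rbinom(n, 1, config$wet_prob)
  prcp <- wet * stats::rgamma(n, shape = config$prcp_shape,
                              scale = config$prcp_scale)
  climate_series(data.frame(date = dates, tmean_c = seasonal + noise,
                            prcp_mm = prcp),
                 site_id = site$site_id)
}

#' Generate monthly drought-index series for all sites
#'
#' Mean-zero AR(1) per site and month, clipped to `[-6, 6]`, covering
#' January of the year before the first observation year through December
#' of the last (so the month before any onset is always available).
#'
#' @param sites [generate_sites()] table.
#' @param years Observation years.
#' @param config A [generator_config()].
#' @param seed Seed for the index substream.
#' @return data.frame: `site_id`, `year`, `month`, `value`.
#' @export
generate_scpdsi <- function(sites, years, config, seed) {
  set.seed(seed %% .Machine$integer.max)
  yrs <- (min(years) - 1L):max(years)
  grid <- expand.grid(month = 1:12, year = yrs)
  n_m <- nrow(grid)
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (config$scpdsi_innov_sd > 0) {
      x0 <- stats::rnorm(1, 0, config$scpdsi_innov_sd /
                           sqrt(1 - config$scpdsi_ar^2))
      innov <- stats::rnorm(n_m, 0, config$scpdsi_innov_sd)
      x <- as.numeric(stats::filter(innov, config$scpdsi_ar,
                                    method = "recursive", init = x0))
    } else x <- numeric(n_m)
    out[[i]] <- data.frame(site_id = sites$site_id[i], year = grid$year,
                           month = grid$month,
                           value = pmin(pmax(x, -6), 6))
  }
  do.call(rbind, out)
}

#' Generate onset observations from the driver-dependent linear model
#'
#' Allocates trees to sites (mild multinomial skew toward mid/high
#' latitudes), species to trees by latitudinal niche affinity, and
#' tree-year records; draws species, site and residual effects once per
#' level/record; then solves the implicit equation
#' `D = round(alpha + beta . X(D) + a_species + b_site + eps)` per record,
#' where the predictors `X(D)` are the drivers accumulated to candidate
#' day `D`. The right-hand side is evaluated on the whole day grid and the
#' emitted onset is its first downward crossing of the identity line — the
#' earliest self-consistent day, matching the phenological reading that
#' onset falls on the first day the accumulated drivers satisfy the model.
#' Records with no crossing, or with a residual mismatch `|rhs(D) - D|`
#' above 2 days at the crossing, are discarded and logged.
#'
#' @param sites,species_table,climates,scpdsi Outputs of the other
#'   generators (climates: named list per `site_id`).
#' @param config A [generator_config()].
#' @return List: `onsets` (tree_id, species, site_id, year, onset_doy),
#'   `truth` (per-record latent effects and drivers at convergence),
#'   `dropped` (non-converged record count). Errors if more than 20% of
#'   records fail to converge.
#' @export
generate_onsets <- function(sites, species_table, climates, scpdsi, config) {
  set.seed(substream(config, "effects"))
  n_sites <- nrow(sites)
  years <- config$years

  # trees -> sites: one tree per site, remainder multinomial with skew
  w <- (0.02 + exp(-(sites$lat - 50)^2 / 200))^config$site_skew
  extra <- as.vector(stats::rmultinom(1, config$n_trees - n_sites,
                                      w / sum(w)))
  trees_per_site <- 1L + extra
  tree_site <- rep(seq_len(n_sites), trees_per_site)
  n_trees <- length(tree_site)

  # species by latitudinal niche affinity
  tree_species <- vapply(tree_site, function(s) {
    p <- exp(-(sites$lat[s] - species_table$niche_lat)^2 /
               (2 * config$niche_sd^2))
    sample.int(nrow(species_table), 1, prob = p)
  }, integer(1))

  # records: one year per tree, remaining tree-years sampled uniformly
  pool <- expand.grid(tree = seq_len(n_trees), year = years)
  first <- vapply(seq_len(n_trees), function(tr) {
    cand <- which(pool$tree == tr)
    cand[sample.int(length(cand), 1)]
  }, integer(1))
  remaining <- setdiff(seq_len(nrow(pool)), first)
  extra_n <- config$n_records - n_trees
  if (extra_n < 0) stop_arg("n_records must be >= n_trees")
  picked <- c(first, sample(remaining, extra_n))
  rec <- pool[picked, ]
  rec <- rec[order(rec$tree, rec$year), ]

  a_sp <- stats::rnorm(nrow(species_table), 0, config$sd_species)
  b_site <- stats::rnorm(n_sites, 0, config$sd_site)
  eps <- stats::rnorm(nrow(rec), 0, config$sd_resid)

  preds <- names(config$betas)
  # base[D] per site-year: alpha + beta . X(D), X from the grids
  grid_cache <- new.env(parent = emptyenv())
  get_grid <- function(s, yr) {
    key <- paste0(s, "_", yr)
    g <- grid_cache[[key]]
    if (is.null(g)) {
      site <- sites[s, ]
      gr <- driver_grids(climates[[site$site_id]], site$lat, yr)
      pdsi_m <- prior_month_values(scpdsi, site$site_id, yr)
      month_of <- as.integer(format(
        seq(as.Date(sprintf("%d-01-01", yr)), by = "day",
            length.out = gr$nd), "%m"))
      X <- cbind(mat = rep(gr$mat, gr$nd), forcing = gr$forcing,
                 chilling = gr$chilling, photoperiod = gr$photoperiod,
                 scpdsi = pdsi_m[month_of])
      g <- list(nd = gr$nd,
                base = config$alpha +
                  as.vector(X[, preds, drop = FALSE] %*% config$betas),
                X = X)
      grid_cache[[key]] <- g
    }
    g
  }

  n_rec <- nrow(rec)
  onset <- integer(n_rec)
  ok <- logical(n_rec)
  why <- character(n_rec)
  truth_X <- matrix(NA_real_, n_rec, 5,
                    dimnames = list(NULL, c("mat", "forcing", "chilling",
                                            "photoperiod", "scpdsi")))
  for (i in seq_len(n_rec)) {
    tr <- rec$tree[i]; s <- tree_site[tr]; yr <- rec$year[i]
    g <- get_grid(s, yr)
    re <- a_sp[tree_species[tr]] + b_site[s] + eps[i]
    rhs <- g$base + re
    nd <- g$nd
    # first downward crossing of rhs(D) - D: the earliest day on which the
    # accumulated drivers satisfy the implicit model
    diff <- rhs - seq_len(nd)
    # candidate solutions: downward crossings of rhs(D) - D (the day the
    # accumulated drivers first satisfy the model), including day 1 when
    # the year starts at or below the line
    cand <- which(diff <= 0 & c(TRUE, diff[-nd] > 0))
    if (length(cand) && cand[1] == 1L && diff[1] < -config$solve_tol) {
      cand <- cand[-1]  # onset would precede the year; try a later crossing
    }
    if (length(cand) == 0L) {
      # no exact solution within the year; accept the nearest-miss day if
      # it is within the solver tolerance (weekly field sampling dates the
      # onset no better than a few days anyway), else discard
      D <- which.min(abs(diff))
      if (abs(diff[D]) > config$solve_tol) {
        ok[i] <- FALSE
        why[i] <- if (diff[1] < -config$solve_tol) "pre_year" else "no_crossing"
        next
      }
    } else {
      cross <- cand[1]
      nb <- max(1L, cross - 1L):cross
      D <- nb[which.min(abs(diff[nb]))]
    }
    onset[i] <- D
    ok[i] <- TRUE
    truth_X[i, ] <- g$X[D, ]
  }

  if (config$obs_error_days > 0) {
    # weekly-sampling dating error: onset is only bracketed by consecutive
    # field visits, so the recorded day scatters around the true one
    err <- sample(seq(-config$obs_error_days, config$obs_error_days),
                  n_rec, replace = TRUE)
    onset <- pmin(pmax(onset + err, 1L), 365L)
  }

  if (mean(!ok) > 0.2) {
    stop_data(sprintf(
      "onset generation failed to converge for %.1f%% of records; review parameters",
      100 * mean(!ok)))
  }
  if (any(!ok)) {
    message(sprintf("generate_onsets: discarded %d non-converged record(s)",
                    sum(!ok)))
  }
  keep <- which(ok)
  drop_log <- data.frame(
    site_id = sites$site_id[tree_site[rec$tree[!ok]]],
    year = rec$year[!ok],
    reason = why[!ok])
  onsets <- data.frame(
    tree_id = sprintf("T%04d", rec$tree[keep]),
    species = species_table$species[tree_species[rec$tree[keep]]],
    site_id = sites$site_id[tree_site[rec$tree[keep]]],
    year = rec$year[keep],
    onset_doy = onset[keep])
  truth <- data.frame(
    onsets[c("tree_id", "species", "site_id", "year", "onset_doy")],
    a_species = a_sp[tree_species[rec$tree[keep]]],
    b_site = b_site[tree_site[rec$tree[keep]]],
    eps = eps[keep],
    truth_X[keep, , drop = FALSE])
  list(onsets = onsets, truth = truth, dropped = sum(!ok),
       drop_log = drop_log)
}

# monthly drought values re-indexed as "value of the month before month m of
# year yr" for m = 1..12
prior_month_values <- function(scpdsi, site_id, yr) {
  vals <- numeric(12)
  for (m in 1:12) {
    pm <- m - 1L; py <- yr
    if (pm == 0L) { pm <- 12L; py <- yr - 1L }
    hit <- scpdsi$site_id == site_id & scpdsi$year == py & scpdsi$month == pm
    vals[m] <- if (any(hit)) scpdsi$value[hit][1] else NA_real_
  }
  if (anyNA(vals)) stop_data("drought-index series does not cover site ",
                             site_id, " year ", yr)
  vals
}

#' Generate a complete synthetic study
#'
#' Runs all generators off one root seed (named substreams per stage) and
#' returns every table the pipeline consumes, plus the latent truth for
#' parameter-recovery testing.
#'
#' @param config A [generator_config()].
#' @return List: `sites`, `species`, `climates` (named list of
#'   [climate_series()]), `scpdsi`, `onsets`, `truth`, `dropped`, `config`.
#' @export
simulate_dataset <- function(config = generator_config()) {
  sites <- generate_sites(config)
  species_table <- generate_species(config)
  climates <- stats::setNames(vector("list", nrow(sites)), sites$site_id)
  for (i in seq_len(nrow(sites))) {
    climates[[i]] <- generate_climate(sites[i, ], config$years, config,
                                      seed = substream(config, "climate") + i)
  }
  scpdsi <- generate_scpdsi(sites, config$years, config,
                            seed = substream(config, "scpdsi"))
  ons <- generate_onsets(sites, species_table, climates, scpdsi, config)
  list(sites = sites, species = species_table, climates = climates,
       scpdsi = scpdsi, onsets = ons$onsets, truth = ons$truth,
       dropped = ons$dropped, drop_log = ons$drop_log, config = config)
}

#' Write a synthetic study to CSV files
#'
#' Writes `sites.csv`, `species.csv`, `onsets.csv`, `scpdsi.csv`,
#' `truth.csv` and one `climate/<site_id>.csv` per site (columns `date`,
#' `tmean_c`, `prcp_mm`) into `dir`.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(file.path(dir, "climate"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  utils::write.csv(sim$species, file.path(dir, "species.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$onsets, file.path(dir, "onsets.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$scpdsi, file.path(dir, "scpdsi.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  for (sid in names(sim$climates)) {
    ser <- sim$climates[[sid]]
    utils::write.csv(as.data.frame(ser)[c("date", "tmean_c", "prcp_mm")],
                     file.path(dir, "climate", paste0(sid, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a study (synthetic or real) from CSV files
#'
#' Inverse of [write_dataset()]: expects `sites.csv`, `onsets.csv`,
#' `scpdsi.csv`, `climate/<site_id>.csv`, and optionally `species.csv`.
#'
#' @param dir Directory holding the CSV layout.
#' @return List with `sites`, `species` (or `NULL`), `onsets`, `scpdsi`,
#'   `climates`.
#' @export
read_dataset <- function(dir) {
  req <- c("sites.csv", "onsets.csv", "scpdsi.csv")
  for (f in req) {
    if (!file.exists(file.path(dir, f))) stop_data("missing input file: ", f)
  }
  sites <- utils::read.csv(file.path(dir, "sites.csv"))
  onsets <- utils::read.csv(file.path(dir, "onsets.csv"))
  scpdsi <- utils::read.csv(file.path(dir, "scpdsi.csv"))
  species_path <- file.path(dir, "species.csv")
  species_table <- if (file.exists(species_path)) {
    utils::read.csv(species_path)
  } else NULL
  climates <- list()
  for (sid in unique(sites$site_id)) {
    f <- file.path(dir, "climate", paste0(sid, ".csv"))
    if (!file.exists(f)) stop_data("missing climate file for site ", sid)
    climates[[sid]] <- climate_series(utils::read.csv(f), site_id = sid)
  }
  list(sites = sites, species = species_table, onsets = onsets,
       scpdsi = scpdsi, climates = climates)
}
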