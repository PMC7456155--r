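#' Configure a pipeline run
#'
#' Either synthetic mode (a [generator_config()] supplies the data) or
#' real-data mode (`data_dir` holds the CSV layout of [read_dataset()]);
#' the two are mutually exclusive.
#'
#' @param out_dir Output directory for all artifacts.
#' @param generator A [generator_config()] for synthetic mode, or `NULL`.
#' @param data_dir Input directory for real-data mode, or `NULL`.
#' @param models Which canonical models to fit (subset of `c(1, 2)`).
#' @param groupings Subgroup analyses to run (subset of
#'   `c("biome", "successional")`).
#' @param windows Chilling windows for the threshold comparison.
#' @param seed Root seed (overrides the generator's seed so one flag
#'   replays a whole run).
#' @return A `run_config` list.
#' @export
pipeline_config <- function(out_dir, generator = generator_config(),
                            data_dir = NULL, models = c(1, 2),
                            groupings = c("biome", "successional"),
                            windows = default_chilling_windows(),
                            seed = NULL) {
  if (!is.null(generator) && !is.null(data_dir)) {
    stop_arg("synthetic mode and real-data mode are mutually exclusive")
  }
  if (is.null(generator) && is.null(data_dir)) {
    stop_arg("either a generator config or a data_dir is required")
  }
  if (!is.null(seed) && !is.null(generator)) generator$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, generator = generator,
                 data_dir = data_dir, models = models, groupings = groupings,
                 windows = windows,
                 seed = if (is.null(seed)) generator$seed else as.integer(seed)),
            class = "run_config")
}

fit_to_list <- function(fit) {
  list(coefficients = fit$coefficients,
       sd_site = fit$sd_site, sd_species = fit$sd_species,
       sd_resid = fit$sd_resid,
       r2_marginal = fit$r2_marginal, r2_conditional = fit$r2_conditional,
       aic = fit$aic, bic = fit$bic, aic_ml = fit$aic_ml, bic_ml = fit$bic_ml,
       loglik = fit$loglik, n_obs = fit$n_obs, method = fit$method,
       singular = fit$singular, dropped_terms = fit$dropped)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", na = "null")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> drivers -> model fits (and subgroups) -> variance
#' partition -> chilling-threshold comparison -> report. Artifacts written
#' to `config$out_dir`: `drivers.csv`, `fit_model1.json`, `fit_model2.json`,
#' subgroup fit JSONs, `partition.json`, `thresholds.csv`, `report.md` and
#' `manifest.json` (config hash, seed, and row counts per stage). Any stage
#' error aborts with the stage name; artifacts from completed stages are
#' kept.
#'
#' @param config A [pipeline_config()].
#' @return List with the in-memory results (`drivers`, `fits`, `subgroups`,
#'   `partition`, `thresholds`, `manifest`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_data(sprintf("pipeline stage '%s' failed: %s", name,
                        conditionMessage(e)))
    })
  }
  manifest <- list(seed = config$seed, stages = list())

  data <- stage("data", {
    if (!is.null(config$generator)) {
      sim <- simulate_dataset(config$generator)
      manifest$config_hash <- config_hash(config$generator)
      sim
    } else {
      ds <- read_dataset(config$data_dir)
      manifest$config_hash <- config_hash(config$data_dir)
      ds
    }
  })
  manifest$stages$onsets <- nrow(data$onsets)
  if (!is.null(data$dropped) && data$dropped > 0) {
    manifest$stages$onset_generation_dropped <- data$dropped
  }

  drivers <- stage("drivers", {
    d <- build_driver_table(data$onsets, data$climates, data$scpdsi,
                            data$sites, species_table = data$species)
    utils::write.csv(d, file.path(out, "drivers.csv"), row.names = FALSE)
    drops <- attr(d, "drops")
    if (nrow(drops) > 0) {
      utils::write.csv(drops, file.path(out, "driver_drops.csv"),
                       row.names = FALSE)
    }
    d
  })
  manifest$stages$drivers <- nrow(drivers)
  manifest$stages$driver_drops <- nrow(attr(drivers, "drops"))

  fits <- list()
  for (m in config$models) {
    nm <- paste0("model", m)
    fits[[nm]] <- stage(paste0("fit_", nm), {
      f <- fit_lmm(drivers, onset_model(m))
      write_json_artifact(fit_to_list(f),
                          file.path(out, paste0("fit_", nm, ".json")))
      f
    })
  }

  subgroups <- list()
  for (g in config$groupings) {
    if (!g %in% names(drivers)) next
    subgroups[[g]] <- stage(paste0("subgroups_", g), {
      sg <- withCallingHandlers(
        fit_subgroups(drivers, onset_model(2), g),
        warning = function(w) invokeRestart("muffleWarning"))
      write_json_artifact(lapply(sg, fit_to_list),
                          file.path(out, paste0("fit_subgroups_", g, ".json")))
      sg
    })
  }

  part <- stage("partition", {
    p <- partition_variance(drivers, onset_model(2))
    write_json_artifact(list(fixed = p$fixed, random = as.list(p$random),
                             residual = p$residual,
                             r2_marginal = p$r2_marginal,
                             r2_conditional = p$r2_conditional,
                             clamped = p$clamped),
                        file.path(out, "partition.json"))
    p
  })

  thresholds <- stage("thresholds", {
    th <- compare_chilling_thresholds(drivers, data$climates, onset_model(2),
                                      config$windows)
    utils::write.csv(th, file.path(out, "thresholds.csv"), row.names = FALSE)
    th
  })

  ranking <- if (length(fits) > 1) compare_models(fits) else NULL
  stage("report", {
    writeLines(render_report(fits, ranking, part, thresholds, drivers),
               file.path(out, "report.md"))
  })
  write_json_artifact(manifest, file.path(out, "manifest.json"))

  invisible(list(drivers = drivers, fits = fits, subgroups = subgroups,
                 partition = part, thresholds = thresholds,
                 ranking = ranking, manifest = manifest))
}

config_hash <- function(x) {
  # md5 of the serialized config; no extra dependency needed
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf)
  unname(tools::md5sum(tf))
}

render_report <- function(fits, ranking, part, thresholds, drivers) {
  fmt_fit <- function(nm, f) {
    cf <- f$coefficients
    c(sprintf("## %s (n = %d, %s)", nm, f$n_obs, f$method),
      "",
      "| term | estimate | SE | p |",
      "|---|---|---|---|",
      sprintf("| %s | %.4g | %.3g | %.3g |", cf$term, cf$estimate, cf$se,
              cf$p_value),
      sprintf("| SD(site) | %.4g | | |", f$sd_site),
      sprintf("| SD(species) | %.4g | | |", f$sd_species),
      sprintf("| SD(residual) | %.4g | | |", f$sd_resid),
      sprintf("| R2m / R2c | %.4g / %.4g | | |", f$r2_marginal,
              f$r2_conditional),
      sprintf("| AIC / BIC | %.6g / %.6g | | |", f$aic, f$bic),
      "")
  }
  lines <- c("# Wood-formation onset: model report", "",
             sprintf("Rows in driver table: %d", nrow(drivers)), "")
  for (nm in names(fits)) lines <- c(lines, fmt_fit(nm, fits[[nm]]))
  if (!is.null(ranking)) {
    lines <- c(lines, "## Model ranking (AIC, BIC tie-break)", "",
               utils::capture.output(print(ranking)), "")
  }
  lines <- c(lines, "## Variance partition (model 2)", "",
             utils::capture.output(print(part)), "",
             "## Chilling-window comparison", "",
             utils::capture.output(print(thresholds)))
  lines
}

#' Binned latitude trend of onset
#'
#' Diagnostic summary of the latitudinal gradient: mean onset DOY and count
#' per latitude bin, plus the record-level Spearman rank correlation
#' between site latitude and onset DOY.
#'
#' @param onsets Onset table (`site_id`, `onset_doy`).
#' @param sites Site table (`site_id`, `lat`).
#' @param n_bins Number of equal-width latitude bins (default 10).
#' @return data.frame of bins with attribute `"rank_correlation"`.
#' @export
latitude_trend <- function(onsets, sites, n_bins = 10L) {
  lat <- sites$lat[match(onsets$site_id, sites$site_id)]
  if (anyNA(lat)) stop_data("onset record refers to an unknown site")
  if (length(unique(sites$lat)) < n_bins) {
    stop_arg("need at least n_bins distinct site latitudes")
  }
  bins <- cut(lat, breaks = seq(min(lat), max(lat), length.out = n_bins + 1),
              include.lowest = TRUE)
  out <- data.frame(
    bin = levels(bins),
    lat_mid = tapply(lat, bins, mean)[levels(bins)],
    mean_onset = tapply(onsets$onset_doy, bins, mean)[levels(bins)],
    n = as.vector(table(bins)[levels(bins)]))
  rownames(out) <- NULL
  attr(out, "rank_correlation") <-
    suppressWarnings(stats::cor(lat, onsets$onset_doy, method = "spearman"))
  out
}
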