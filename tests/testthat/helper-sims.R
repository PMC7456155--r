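# Shared full-scale simulation cache. The 20-seed recovery, threshold and
# model-selection acceptance criteria all consume the same generator
# defaults; generation is the expensive stage, so each seed's dataset and
# driver table are built once per session and reused.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(seed) {
  key <- paste0("s", seed)
  got <- .sim_cache[[key]]
  if (!is.null(got)) return(got)
  sim <- suppressMessages(simulate_dataset(generator_config(seed = seed)))
  drivers <- suppressMessages(
    build_driver_table(sim$onsets, sim$climates, sim$scpdsi, sim$sites,
                       species_table = sim$species))
  got <- list(sim = sim, drivers = drivers)
  .sim_cache[[key]] <- got
  got
}

# small-but-crossed design for fast lmm/partition tests
small_config <- function(seed = 1, ...) {
  generator_config(n_sites = 15L, n_species = 8L, n_trees = 60L,
                   n_records = 200L, years = 2006:2012, seed = seed, ...)
}

cached_small <- function(seed = 1) {
  key <- paste0("small", seed)
  got <- .sim_cache[[key]]
  if (!is.null(got)) return(got)
  sim <- suppressMessages(simulate_dataset(small_config(seed)))
  drivers <- suppressMessages(
    build_driver_table(sim$onsets, sim$climates, sim$scpdsi, sim$sites,
                       species_table = sim$species))
  got <- list(sim = sim, drivers = drivers)
  .sim_cache[[key]] <- got
  got
}
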