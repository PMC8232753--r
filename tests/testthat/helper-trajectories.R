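# Simulated trajectories reused across test files (the engine is
# deterministic, so one run per scenario suffices).
.traj_cache <- new.env(parent = emptyenv())

cached_traj <- function(name, config = NULL) {
  if (!exists(name, envir = .traj_cache)) {
    cfg <- if (is.null(config)) preset(name) else config
    assign(name, simulate_culture(cfg), envir = .traj_cache)
  }
  get(name, envir = .traj_cache)
}

# single-cohort scenarios with known true n, for detector recovery tests
single_cohort_traj <- function(n) {
  key <- paste0("single_", n)
  cfg <- switch(as.character(n),
    "1" = preset("fig5_110", cohort_fractions = c("1" = 1)),
    "2" = preset("fig5_110"),
    "3" = preset("fig5_250", cohort_fractions = c("3" = 1)),
    "4" = preset("fig5_500"))
  cached_traj(key, cfg)
}
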