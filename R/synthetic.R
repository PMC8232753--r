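# Synthetic synchronized-culture observations and packaged reference
# tables, so every statistic is testable without any external data.

#' Multiplicative lognormal measurement-noise model
#'
#' Replicated assays of positive quantities (cell counts, OD, DNA, starch)
#' are emulated with multiplicative lognormal noise of unit mean:
#' `replicate = true * exp(rnorm(sdlog) - sdlog^2/2)` with
#' `sdlog = sqrt(log(1 + cv^2))`.
#'
#' @param cv Coefficient of variation, `>= 0` (default 5%).
#' @param replicates Number of replicates per sample (default 3, the
#'   replicate structure of the assays emulated).
#' @param sampling_interval Sampling interval (h), default 1.
#' @param seed Integer RNG seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(cv = 0.05, replicates = 3, sampling_interval = 1,
                        seed = 1) {
  if (cv < 0) stop("cv must be nonnegative")
  if (replicates < 1) stop("at least one replicate is required")
  if (sampling_interval <= 0) stop("sampling interval must be positive")
  structure(list(cv = cv, replicates = as.integer(replicates),
                 sampling_interval = sampling_interval,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate noisy replicate observations from a simulated trajectory
#'
#' Samples the trajectory on the noise model's grid and perturbs every
#' observable independently per replicate with unit-mean lognormal noise.
#' The OD750 proxy is an affine image of dry matter scaled so that the
#' initial OD is 0.25 (OD enters the statistics only through ratios, so the
#' scale is arbitrary). Identical seeds give identical output.
#'
#' @param traj A `culture_trajectory` from [simulate_culture()].
#' @param noise A [noise_model()].
#' @return An `observation_series`: long data frame with columns
#'   `time_h, replicate, observable, value` plus metadata attributes.
#' @export
generate_observations <- function(traj, noise = noise_model()) {
  stopifnot(inherits(traj, "culture_trajectory"),
            inherits(noise, "noise_model"))
  dt <- traj$config$time_step
  if (noise$sampling_interval < dt - 1e-12) {
    stop("sampling interval must not be finer than the engine time step")
  }
  tr <- traj$trajectory
  grid <- seq(0, max(tr$time_h), by = noise$sampling_interval)
  idx <- vapply(grid, function(tt) which.min(abs(tr$time_h - tt)), integer(1))
  truth <- data.frame(
    time_h = tr$time_h[idx],
    cell_conc = tr$cell_conc_1e6_per_ml[idx],
    od750 = 0.25 * tr$dry_matter_ug_per_ml[idx] / tr$dry_matter_ug_per_ml[1],
    dna_pg_per_cell = tr$dna_pg_per_cell[idx],
    rna_rel = tr$rna_rel[idx],
    dry_matter = tr$dry_matter_ug_per_ml[idx],
    volume_um3 = tr$volume_um3[idx],
    starch = tr$starch_ug_per_ml[idx])
  obs_names <- setdiff(names(truth), "time_h")
  sdlog <- sqrt(log(1 + noise$cv^2))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(noise$seed)
  out <- vector("list", noise$replicates)
  for (r in seq_len(noise$replicates)) {
    vals <- lapply(obs_names, function(nm) {
      x <- truth[[nm]]
      if (noise$cv == 0) return(x)
      x * exp(stats::rnorm(length(x), mean = -sdlog^2 / 2, sd = sdlog))
    })
    out[[r]] <- data.frame(
      time_h = rep(truth$time_h, length(obs_names)),
      replicate = r,
      observable = rep(obs_names, each = nrow(truth)),
      value = unlist(vals))
  }
  res <- do.call(rbind, out)
  attr(res, "noise") <- noise
  attr(res, "scenario") <- traj$config$I_i
  class(res) <- c("observation_series", "data.frame")
  res
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Replicate means of an observation series
#'
#' @param obs An `observation_series`.
#' @param observable Which observable to extract.
#' @return Data frame `time_h, value` of replicate means.
#' @export
observation_means <- function(obs, observable) {
  sub <- obs[obs$observable == observable, , drop = FALSE]
  if (!nrow(sub)) stop("unknown observable: ", observable)
  agg <- stats::aggregate(value ~ time_h, data = sub, FUN = mean)
  agg[order(agg$time_h), ]
}

#' Packaged division and mass reference tables
#'
#' The two reference tables of the deuterated-water experiments: division
#' number and cell-number doubling time (`table_fixtures("division")`), and
#' mass multiplication factor and mass doubling time
#' (`table_fixtures("mass")`), for cultures in 0, 70 and 99% heavy water
#' (the latter also pre-adapted) at incident intensities 150-400
#' umol photons m^-2 s^-1. Unreliable cells (cell death and lysis) are NA.
#'
#' @param which `"division"` or `"mass"`.
#' @return Data frame of 16 rows (4 heavy-water conditions x 4 light
#'   intensities).
#' @export
table_fixtures <- function(which = c("division", "mass")) {
  which <- match.arg(which)
  file <- if (which == "division") "table1_division.csv" else "table2_mass.csv"
  path <- system.file("extdata", file, package = "multifission",
                      mustWork = TRUE)
  utils::read.csv(path)
}

#' Packaged scenario constants
#'
#' The printed experimental constants used for calibration and checks:
#' initial culture state, the light/dry-matter endpoint anchors, per-cycle
#' DNA bounds and the synchronization schedule.
#'
#' @return Data frame with columns `name`, `value`, `units`, `context`.
#' @export
scenario_constants <- function() {
  data.frame(
    name = c("initial_dry_matter", "final_dry_matter_500",
             "final_dry_matter_250", "final_dry_matter_110",
             "mean_light_initial_500", "mean_light_initial_250",
             "mean_light_initial_110", "mean_light_final_500",
             "mean_light_final_250", "mean_light_final_110",
             "initial_dna", "final_dna_500", "initial_cell_volume",
             "light_on", "light_off", "max_sequences"),
    value = c(100, 1600, 1300, 400, 360, 180, 80, 160, 85, 50,
              0.1, 1.6, 25, 18, 7, 4),
    units = c(rep("ug/mL", 4), rep("umol photons m-2 s-1", 6),
              "pg/cell", "pg/cell", "um^3", "h", "h", "sequences"),
    context = c(rep("dry-matter anchors", 4), rep("light anchors", 6),
                rep("DNA per cell", 2), "initial cell size",
                rep("synchronization schedule", 2), "division capacity"))
}
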