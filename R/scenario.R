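# Scenario configuration: everything the culture engine needs to run one
# synchronized cell cycle. All durations in hours.

#' Multiple-fission pattern identifiers
#'
#' Closed enumeration of the four reproductive-sequence timings handled by
#' the engine:
#' \describe{
#'   \item{CONSECUTIVE_SCENEDESMUS}{each reproductive sequence runs
#'     pS-S-G2-M-G3 independently after its own commitment point; cells pass
#'     through bi-, tetra-, ... 2^n-nuclear stages; fissions deferred to the
#'     end of the final sequence.}
#'   \item{CLUSTERED_CHLAMYDOMONAS}{no DNA replication before the final
#'     commitment point; then rapid S-M alternations, each replication
#'     immediately followed by its nuclear division; per-nucleus ploidy never
#'     exceeds 2C.}
#'   \item{HAEMATOCOCCUS}{all replication rounds first (polyploidization),
#'     then all nuclear divisions (polynuclear stage), then all protoplast
#'     fissions.}
#'   \item{PARACHLORELLA}{all replication rounds first (uni-nuclear
#'     polyploidization up to 2^n C), then n alternations of nuclear division
#'     each immediately followed by protoplast fission (no G3), so no more
#'     than two nuclei ever coexist in one cell.}
#' }
#' @export
pattern_types <- function() {
  c("CONSECUTIVE_SCENEDESMUS", "CLUSTERED_CHLAMYDOMONAS",
    "HAEMATOCOCCUS", "PARACHLORELLA")
}

#' Cell-cycle phase durations
#'
#' Durations (hours) of the phases of one reproductive sequence, plus the
#' minimum spacing between consecutive DNA replication rounds for patterns
#' that chain them. `pS` separates the first commitment point from the first
#' replication round; subsequent rounds are gated by `inter_S_gap` (and never
#' start before their own commitment point). The default 2 h gap matches the
#' pause observed between successive DNA duplications in synchronized
#' cultures.
#'
#' @param pS Pre-replication phase after the first commitment point (h).
#' @param S Duration of one DNA replication round (h).
#' @param G2 Gap between the end of replication and the first mitosis (h).
#' @param M Duration of one nuclear division (h).
#' @param G3 Gap between mitosis and protoplast fission (h); 0 for the
#'   Parachlorella pattern, whose fissions follow mitoses immediately.
#' @param C Duration of one protoplast fission / daughter-formation step (h).
#' @param inter_S_gap Minimum spacing between consecutive replication
#'   rounds (h).
#' @return A `phase_durations` list.
#' @export
phase_durations <- function(pS = 7, S = 1, G2 = 0.5, M = 0.5, G3 = 0,
                            C = 0.5, inter_S_gap = 2) {
  vals <- c(pS = pS, S = S, G2 = G2, M = M, G3 = G3, C = C,
            inter_S_gap = inter_S_gap)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("phase durations must be finite and nonnegative")
  }
  structure(as.list(vals), class = "phase_durations")
}

#' Light response of biomass growth
#'
#' Specific growth rate follows a Monod (saturating) response to the mean
#' light intensity, `mu(I_m) = mu_max * I_m / (K_I + I_m)`, and is zero in
#' the dark. Growth steps are separated by idle intervals whose length
#' shrinks with light: `idle_base / (1 + idle_light_scaling * I_m / K_I)`,
#' reproducing the long no-growth gaps of dim cultures and the almost
#' indistinguishable gaps of bright ones.
#'
#' @param mu_max Maximal specific growth rate (h^-1).
#' @param K_I Half-saturation intensity (umol photons m^-2 s^-1).
#' @param idle_base No-growth interval between steps at vanishing light (h).
#' @param idle_light_scaling Dimensionless shrink factor of the idle
#'   interval with light.
#' @return A `growth_params` list.
#' @export
growth_params <- function(mu_max = 0.42, K_I = 100, idle_base = 6,
                          idle_light_scaling = 2.5) {
  if (mu_max <= 0) stop("mu_max must be positive")
  if (K_I <= 0) stop("K_I must be positive")
  if (idle_base < 0) stop("idle_base must be nonnegative")
  if (idle_light_scaling < 0) stop("idle_light_scaling must be nonnegative")
  structure(list(mu_max = mu_max, K_I = K_I, idle_base = idle_base,
                 idle_light_scaling = idle_light_scaling),
            class = "growth_params")
}

#' Net-starch reserve parameters
#'
#' Culture-level net starch changes as
#' `d(starch)/dt = biomass * sigma_max * Ie / (K_sigma + Ie)` in the light,
#' where `Ie = max(I_m - compensation, 0)` is the mean intensity in excess of
#' the light-compensation level below which photosynthate is fully consumed
#' by maintenance and synthesis. Each protoplast fission consumes a fixed
#' fraction `division_cost` of the current starch pool (scaled by the
#' population fraction dividing), and in the dark the pool decays at the
#' first-order rate `maintenance_dark`.
#'
#' @param sigma_max Light-saturated net synthesis scale
#'   (ug starch per ug dry matter per h).
#' @param K_sigma Half-saturation of the light response
#'   (umol photons m^-2 s^-1, on the excess intensity).
#' @param compensation Light-compensation intensity (umol photons m^-2 s^-1)
#'   below which there is no net synthesis.
#' @param division_cost Fraction of the starch pool consumed per fission
#'   event, in `[0, 1]`.
#' @param maintenance_dark First-order dark consumption rate (h^-1).
#' @param initial Initial culture starch (ug mL^-1).
#' @return A `starch_params` list.
#' @export
starch_params <- function(sigma_max = 0.01229, K_sigma = 5,
                          compensation = 50.8, division_cost = 0.1,
                          maintenance_dark = 0.02, initial = 10) {
  vals <- c(sigma_max, K_sigma, compensation, maintenance_dark, initial)
  if (any(vals < 0)) stop("starch parameters must be nonnegative")
  if (division_cost < 0 || division_cost > 1) {
    stop("division_cost must be in [0, 1]")
  }
  structure(list(sigma_max = sigma_max, K_sigma = K_sigma,
                 compensation = compensation, division_cost = division_cost,
                 maintenance_dark = maintenance_dark, initial = initial),
            class = "starch_params")
}

#' Scenario configuration for one synchronized culture cycle
#'
#' Bundles every constant the engine needs. Cohort fractions represent
#' deterministic population heterogeneity: `cohort_fractions = c("3" = 0.5,
#' "4" = 0.5)` means half the mothers complete three reproductive sequences
#' and half complete four. Retardation models deuterium stress as two
#' scalars: `rho_growth` divides the specific growth rate and
#' `rho_division` multiplies all phase durations.
#'
#' @param I_i Incident light intensity (umol photons m^-2 s^-1).
#' @param light_schedule Either `"continuous"` or a numeric vector
#'   `c(on, off)` of light/dark durations (h), repeated cyclically. The
#'   synchronization regime of the study is `c(18, 7)`.
#' @param pattern One of [pattern_types()].
#' @param initial_dry_matter Initial dry matter (ug mL^-1).
#' @param initial_cell_conc Initial cell concentration (10^6 cells mL^-1).
#' @param initial_DNA Initial DNA per cell (pg).
#' @param initial_cell_volume Initial mean cell volume (um^3).
#' @param phase A [phase_durations()].
#' @param growth A [growth_params()].
#' @param attenuation An [attenuation_model()]; default calibrated from the
#'   packaged endpoint anchors.
#' @param max_sequences Cap on the number of reproductive sequences n.
#' @param cohort_fractions Named numeric vector mapping n to the fraction of
#'   mothers completing n sequences; must sum to 1.
#' @param starch A [starch_params()].
#' @param retardation Numeric `c(rho_growth, rho_division)`, both `>= 1`.
#' @param rna_doubling_cap Cap on RNA doublings (bulk RNA saturates after
#'   three doublings even when volume and dry matter double four times).
#' @param time_step Integration step (h).
#' @param horizon Simulated time span (h); default one full 18 h light +
#'   7 h dark cycle.
#' @return A `scenario_config` list (validated).
#' @export
scenario_config <- function(I_i = 500,
                            light_schedule = c(18, 7),
                            pattern = "PARACHLORELLA",
                            initial_dry_matter = 100,
                            initial_cell_conc = 1,
                            initial_DNA = 0.1,
                            initial_cell_volume = 25,
                            phase = phase_durations(),
                            growth = growth_params(),
                            attenuation = default_attenuation_model(),
                            max_sequences = 4,
                            cohort_fractions = c("4" = 1),
                            starch = starch_params(),
                            retardation = c(rho_growth = 1, rho_division = 1),
                            rna_doubling_cap = 3,
                            time_step = 0.05,
                            horizon = 25) {
  cfg <- structure(list(
    I_i = I_i, light_schedule = light_schedule, pattern = pattern,
    initial_dry_matter = initial_dry_matter,
    initial_cell_conc = initial_cell_conc,
    initial_DNA = initial_DNA, initial_cell_volume = initial_cell_volume,
    phase = phase, growth = growth, attenuation = attenuation,
    max_sequences = max_sequences, cohort_fractions = cohort_fractions,
    starch = starch, retardation = retardation,
    rna_doubling_cap = rna_doubling_cap,
    time_step = time_step, horizon = horizon), class = "scenario_config")
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  if (!inherits(cfg, "scenario_config")) stop("not a scenario_config")
  if (cfg$I_i <= 0) stop("incident intensity must be positive")
  if (!cfg$pattern %in% pattern_types()) {
    stop("unknown pattern: ", cfg$pattern)
  }
  if (!identical(cfg$light_schedule, "continuous")) {
    ls <- cfg$light_schedule
    if (!is.numeric(ls) || length(ls) != 2L || any(ls < 0) || ls[1] <= 0) {
      stop("light_schedule must be \"continuous\" or c(on, off) hours")
    }
  }
  pos <- c(initial_dry_matter = cfg$initial_dry_matter,
           initial_cell_conc = cfg$initial_cell_conc,
           initial_DNA = cfg$initial_DNA,
           initial_cell_volume = cfg$initial_cell_volume,
           time_step = cfg$time_step, horizon = cfg$horizon)
  if (any(pos <= 0)) {
    stop("nonpositive scenario constant: ",
         paste(names(pos)[pos <= 0], collapse = ", "))
  }
  cf <- cfg$cohort_fractions
  if (is.null(names(cf)) || any(is.na(suppressWarnings(as.integer(names(cf)))))) {
    stop("cohort_fractions must be named by integer sequence counts")
  }
  if (any(cf < 0)) stop("cohort fractions must be nonnegative")
  if (abs(sum(cf) - 1) > 1e-9) stop("cohort fractions must sum to 1")
  ns <- as.integer(names(cf))
  if (any(ns < 0)) stop("sequence counts must be nonnegative")
  if (any(ns > cfg$max_sequences)) {
    stop("cohort sequence count exceeds max_sequences")
  }
  if (any(cfg$retardation < 1)) stop("retardation factors must be >= 1")
  stopifnot(inherits(cfg$phase, "phase_durations"),
            inherits(cfg$growth, "growth_params"),
            inherits(cfg$starch, "starch_params"),
            inherits(cfg$attenuation, "attenuation_model"))
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  sched <- if (identical(x$light_schedule, "continuous")) "continuous light"
           else sprintf("%gL:%gD", x$light_schedule[1], x$light_schedule[2])
  cat(sprintf("Scenario: I_i = %g uE, %s, pattern %s\n",
              x$I_i, sched, x$pattern))
  cat(sprintf("  cohorts: %s\n",
              paste(sprintf("n=%s: %.2f", names(x$cohort_fractions),
                            x$cohort_fractions), collapse = ", ")))
  cat(sprintf("  initial: %g ug/mL dry matter, %g x10^6 cells/mL, %g pg DNA, %g um^3\n",
              x$initial_dry_matter, x$initial_cell_conc, x$initial_DNA,
              x$initial_cell_volume))
  cat(sprintf("  horizon %g h at dt = %g h\n", x$horizon, x$time_step))
  invisible(x)
}

#' Named scenario presets
#'
#' `preset_names()` lists the packaged scenarios; `preset(name, ...)`
#' constructs one (dots override any [scenario_config()] argument).
#'
#' * `fig5_500`, `fig5_250`, `fig5_110`: the three synchronized-culture light
#'   treatments (18L:7D). At 500 uE all mothers complete four reproductive
#'   sequences; at 250 uE the population splits half/half between three and
#'   four; at 110 uE all complete two.
#' * `sync_18L7D`: alias of the optimal-light synchronization regime.
#' * `continuous_control`: continuous light control at 150 uE used as the
#'   no-deuterium reference of the stress experiments.
#' * `d2o_70`, `d2o_99`, `d2o_99_adapted`: continuous-light deuterated-water
#'   scenarios; retardation factors are the mean fold retardations of mass
#'   (growth) and cell-number (division) doubling times observed at 70%,
#'   99% and pre-adapted 99% heavy water.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [scenario_config()].
#' @return `preset()`: a `scenario_config`; `preset_names()`: character.
#' @export
preset <- function(name, ...) {
  name <- match.arg(name, preset_names())
  base <- switch(name,
    fig5_500 = list(I_i = 500, cohort_fractions = c("4" = 1)),
    fig5_250 = list(I_i = 250, cohort_fractions = c("3" = 0.5, "4" = 0.5)),
    fig5_110 = list(I_i = 110, cohort_fractions = c("2" = 1)),
    sync_18L7D = list(I_i = 500, cohort_fractions = c("4" = 1)),
    continuous_control = list(I_i = 150, light_schedule = "continuous",
                              cohort_fractions = c("3" = 1), horizon = 30),
    d2o_70 = list(I_i = 150, light_schedule = "continuous",
                  cohort_fractions = c("2" = 1),
                  retardation = c(rho_growth = 1.20, rho_division = 1.55),
                  horizon = 60),
    d2o_99 = list(I_i = 150, light_schedule = "continuous",
                  cohort_fractions = c("1" = 1),
                  retardation = c(rho_growth = 18.3, rho_division = 14.4),
                  horizon = 300, time_step = 0.25),
    d2o_99_adapted = list(I_i = 150, light_schedule = "continuous",
                          cohort_fractions = c("1" = 1),
                          retardation = c(rho_growth = 3.93, rho_division = 4.27),
                          horizon = 90)
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(scenario_config, base)
}

#' @rdname preset
#' @export
preset_names <- function() {
  c("fig5_500", "fig5_250", "fig5_110", "sync_18L7D", "continuous_control",
    "d2o_70", "d2o_99", "d2o_99_adapted")
}

# TRUE iff the light is on at time t (start of interval) under the schedule.
light_on_at <- function(t, schedule) {
  if (identical(schedule, "continuous")) return(rep(TRUE, length(t)))
  period <- sum(schedule)
  if (schedule[2] == 0) return(rep(TRUE, length(t)))
  (t %% period) < schedule[1] - 1e-12
}
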