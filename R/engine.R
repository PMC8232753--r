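# Deterministic event-driven culture engine.
#
# The simulation runs in three exact passes over a fixed time grid:
#   A. biomass growth with light feedback -> commitment-point times,
#   B. pattern-lawful scheduling of the reproductive events (schedule.R),
#   C. application of the events to per-cell state (DNA, nuclei, ploidy),
#      cell concentration, and the starch reserve.
# Growth does not depend on the reproductive events and the light field
# depends only on dry matter, so the decomposition is lossless. There is no
# randomness anywhere in the engine.

#' Specific growth rate under a given mean light intensity
#'
#' Monod response divided by the deuterium growth-retardation factor:
#' `mu = mu_max * I_m / (K_I + I_m) / rho_growth`. Zero in the dark.
#'
#' @param I_m Mean light intensity (umol photons m^-2 s^-1), `>= 0`.
#' @param g A [growth_params()].
#' @param rho_growth Growth retardation factor, `>= 1` (1 = no stress).
#' @return Specific rate (h^-1).
#' @export
growth_rate <- function(I_m, g = growth_params(), rho_growth = 1) {
  if (any(I_m < 0)) stop("mean intensity must be nonnegative")
  if (any(rho_growth < 1)) stop("rho_growth must be >= 1")
  (g$mu_max * I_m / (g$K_I + I_m)) / rho_growth
}

# Fresh per-cell growth state: proxies relative to the cycle start.
new_growth_state <- function(rna_cap = 3) {
  list(rna = 1, dry_matter = 1, volume = 1,
       steps_done = 0L, committed = 0L, cp_times = numeric(0),
       mode = "growing", step_start_volume = 1,
       idle_remaining = 0, rna_cap = rna_cap, pending_cp = FALSE)
}

#' Advance the growth state of one cell over a small time step
#'
#' Multiplies the biomass proxies (bulk RNA, dry matter, cell volume;
#' relative to the cycle start) by `exp(rate * dt)` while a growth step is
#' active. When the reference proxy (cell volume) reaches twice its value at
#' step start, the step completes at the end of this interval: proxies are
#' set to exact doublings, a commitment point fires (in the light; a
#' completion coinciding with darkening commits only when light returns),
#' and an idle no-growth interval of length `idle_length` is inserted before
#' the next step. In the dark, or during idle, proxies are frozen. Bulk RNA
#' stops doubling after `rna_cap` steps.
#'
#' @param state Growth state list as produced by previous calls (pass
#'   `state = NULL` to start a fresh cell).
#' @param dt Time step (h), `> 0`.
#' @param rate Specific growth rate over this interval (h^-1).
#' @param idle_length Idle interval to insert if a step completes now (h).
#' @param light_on Is the light on during this interval?
#' @param max_steps Stop growing after this many completed steps.
#' @return Updated state; `state$cp_fired` is TRUE when a commitment point
#'   fired at the end of this interval.
#' @export
advance_growth <- function(state, dt, rate, idle_length = 0,
                           light_on = TRUE, max_steps = Inf,
                           light_at_end = light_on) {
  if (is.null(state)) state <- new_growth_state()
  if (dt <= 0) stop("dt must be positive")
  state$cp_fired <- FALSE
  fire_cp <- function(state) {
    state$committed <- state$committed + 1L
    tn <- if (is.null(state$t_next)) NA_real_ else state$t_next
    state$cp_times <- c(state$cp_times, tn)
    state$cp_fired <- TRUE
    state$pending_cp <- FALSE
    state
  }
  if (state$mode == "done" || state$steps_done >= max_steps) {
    state$mode <- "done"
    return(state)
  }
  if (!light_on) {
    return(state)  # frozen: no growth, no idle countdown, no commitment
  }
  if (state$pending_cp) {
    # step completed at a dark boundary; commit at the first lit instant
    state <- fire_cp(state)
    if (state$steps_done >= max_steps) {
      state$mode <- "done"
      return(state)
    }
    state$mode <- "idle"
    state$idle_remaining <- idle_length
  }
  if (state$mode == "idle") {
    state$idle_remaining <- state$idle_remaining - dt
    if (state$idle_remaining <= 1e-9) {
      state$mode <- "growing"
      state$step_start_volume <- state$volume
      state$idle_remaining <- 0
    }
    return(state)
  }
  # growing
  f <- exp(rate * dt)
  target <- 2 * state$step_start_volume
  if (state$volume * f >= target * (1 - 1e-12)) {
    s <- state$steps_done + 1L
    state$steps_done <- s
    state$volume <- 2^s
    state$dry_matter <- 2^s
    state$rna <- 2^min(s, state$rna_cap)
    if (!light_at_end) {
      # completion coincides with darkening: no commitment in the dark
      state$pending_cp <- TRUE
      state$mode <- "idle"
      state$idle_remaining <- 0
    } else {
      state <- fire_cp(state)
      if (s >= max_steps) {
        state$mode <- "done"
      } else {
        state$mode <- "idle"
        state$idle_remaining <- idle_length
      }
    }
  } else {
    state$volume <- state$volume * f
    state$dry_matter <- state$dry_matter * f
    if (state$steps_done < state$rna_cap) state$rna <- state$rna * f
  }
  state
}

#' One integration step of the net-starch reserve
#'
#' In the light, net synthesis is `dt * biomass * sigma_max * Ie /
#' (K_sigma + Ie)` with `Ie = max(I_m - compensation, 0)`; in the dark the
#' pool decays exponentially at `maintenance_dark`. A fission event consumes
#' the fraction `division_cost * dividing_fraction` of the pool. The pool is
#' clamped at zero (with a warning) should parameters drive it negative.
#'
#' @param starch Current culture starch (ug mL^-1).
#' @param dt Time step (h), `> 0`.
#' @param I_m Mean light intensity (0 in the dark).
#' @param biomass Culture dry matter (ug mL^-1).
#' @param p A [starch_params()].
#' @param dividing_fraction Population fraction undergoing a fission event
#'   at the end of this interval (0 = no fission).
#' @return Updated starch value.
#' @export
starch_step <- function(starch, dt, I_m, biomass, p = starch_params(),
                        dividing_fraction = 0) {
  if (dt <= 0) stop("dt must be positive")
  if (I_m > 0) {
    Ie <- max(I_m - p$compensation, 0)
    starch <- starch + dt * biomass * p$sigma_max * Ie / (p$K_sigma + Ie)
  } else {
    starch <- starch * exp(-p$maintenance_dark * dt)
  }
  if (dividing_fraction > 0) {
    starch <- starch * (1 - p$division_cost * dividing_fraction)
  }
  if (starch < 0) {
    warning("starch clamped at zero")
    starch <- 0
  }
  starch
}

#' Simulate one synchronized multiple-fission culture cycle
#'
#' Fixed-step integration of growth, self-shading light feedback and the
#' starch reserve, with reproductive events scheduled per cohort by
#' [schedule_reproduction()]. Commitment points fire only in the light;
#' committed sequences run to completion regardless of light (cells darkened
#' during protoplast fission still form and release their daughters). At
#' `DAUGHTER_RELEASE` the cell concentration of a cohort multiplies by
#' `2^n`, per-cell DNA resets to the initial amount and per-cell biomass
#' proxies divide by `2^n`; culture-level dry matter is continuous across
#' the release. Event times are snapped to the integration grid
#' (earliest-grid-point-after); simultaneous events are ordered
#' CP < S < M < FISSION < RELEASE.
#'
#' @param config A [scenario_config()].
#' @return A `culture_trajectory` object: list with `trajectory` (data frame
#'   sampled at `time_step`: `time_h, cell_conc_1e6_per_ml,
#'   dry_matter_ug_per_ml, mean_light, dna_pg_per_cell, rna_rel, volume_um3,
#'   starch_ug_per_ml, nuclei, ploidy_C`), `events` (event log with a
#'   `cohort` column), `cohorts` (per-cohort summary), `config`, and a
#'   `truncated` flag (TRUE, with a warning, when the horizon cuts a
#'   committed sequence short).
#' @export
simulate_culture <- function(config) {
  cfg <- validate_scenario(config)
  dt <- cfg$time_step
  times <- seq(0, cfg$horizon, by = dt)
  nt <- length(times)
  rho_g <- cfg$retardation[[1]]
  rho_d <- cfg$retardation[[2]]
  fracs <- cfg$cohort_fractions
  n_targets <- as.integer(names(fracs))
  nc <- length(fracs)
  g <- cfg$growth

  ## Pass A: growth with light feedback ------------------------------------
  states <- lapply(seq_len(nc), function(i) new_growth_state(cfg$rna_doubling_cap))
  dm_rel <- matrix(1, nt, nc)    # per-cell dry matter, relative
  vol_rel <- matrix(1, nt, nc)
  rna_rel <- matrix(1, nt, nc)
  I_m <- numeric(nt)
  light <- light_on_at(times, cfg$light_schedule)
  culture_dm <- function(i) {
    cfg$initial_dry_matter * sum(fracs * dm_rel[i, ])
  }
  for (i in seq_len(nt)) {
    X <- culture_dm(i)
    I_m[i] <- if (light[i]) {
      mean_light_intensity(cfg$I_i, transmitted_intensity(cfg$I_i, X, cfg$attenuation))
    } else 0
    if (i == nt) break
    rate <- growth_rate(I_m[i], g, rho_g)
    idle_len <- g$idle_base / (1 + g$idle_light_scaling * I_m[i] / g$K_I)
    for (c in seq_len(nc)) {
      st <- states[[c]]
      st$t_next <- times[i + 1]
      st <- advance_growth(st, dt, rate, idle_length = idle_len,
                           light_on = light[i], max_steps = n_targets[c],
                           light_at_end = light[i + 1])
      states[[c]] <- st
      dm_rel[i + 1, c] <- st$dry_matter
      vol_rel[i + 1, c] <- st$volume
      rna_rel[i + 1, c] <- st$rna
    }
  }
  X_series <- cfg$initial_dry_matter * as.vector(dm_rel %*% fracs)

  ## Pass B: reproductive schedules per cohort ------------------------------
  phase_r <- cfg$phase
  for (nm in c("pS", "S", "G2", "M", "G3", "C", "inter_S_gap")) {
    phase_r[[nm]] <- phase_r[[nm]] * rho_d
  }
  snap <- function(tt) times[pmin(nt, findInterval(tt - 1e-9, times) + 1L)]
  logs <- vector("list", nc)
  truncated <- FALSE
  for (c in seq_len(nc)) {
    cp <- states[[c]]$cp_times
    log <- schedule_reproduction(cfg$pattern, cp, phase_r)
    if (nrow(log)) {
      if (max(log$time) > cfg$horizon + 1e-9) {
        truncated <- TRUE
        log <- log[log$time <= cfg$horizon + 1e-9, , drop = FALSE]
      }
      log$time <- snap(log$time)
      log <- sort_event_log(log)
    }
    logs[[c]] <- log
  }
  if (truncated) {
    warning("horizon ends before all committed sequences complete; ",
            "trajectory truncated")
  }

  ## Pass C: per-cell state, cell counts, starch ----------------------------
  dna_rel <- matrix(1, nt, nc)     # per-compartment DNA, relative to initial
  nuclei <- matrix(1, nt, nc)
  ploidy <- matrix(1, nt, nc)
  comp <- matrix(1, nt, nc)        # protoplast compartments per mother
  cellsf <- matrix(1, nt, nc)      # released cells per mother (1 until release)
  released <- logical(nc)
  release_time <- rep(NA_real_, nc)
  fission_frac <- numeric(nt)      # population fraction dividing at each grid point
  for (c in seq_len(nc)) {
    log <- logs[[c]]
    if (!nrow(log)) next
    cur <- list(dna = 1, nuc = 1, plo = 1)
    ev_i <- 1L
    # stepwise fill between events; linear DNA ramp during S
    for (j in seq_len(nrow(log))) {
      ev <- log[j, ]
      idx <- which(times >= ev$time - 1e-9)[1]
      if (is.na(idx)) next
      switch(ev$event,
        CP = NULL,
        S_START = NULL,
        S_END = {
          # ramp DNA linearly from the matching S_START to here
          start_t <- log$time[log$event == "S_START" & log$seq == ev$seq]
          i0 <- which(times >= start_t - 1e-9)[1]
          from <- dna_rel[i0, c]
          ii <- i0:idx
          if (length(ii) > 1) {
            dna_rel[ii, c] <- from + (ev$dna_rel - from) *
              (times[ii] - times[i0]) / max(times[idx] - times[i0], dt)
          }
          dna_rel[idx:nt, c] <- ev$dna_rel
          ploidy[idx:nt, c] <- ev$ploidy_c
          nuclei[idx:nt, c] <- ev$nuclei
        },
        M = {
          nuclei[idx:nt, c] <- ev$nuclei
          ploidy[idx:nt, c] <- ev$ploidy_c
        },
        FISSION = {
          nuclei[idx:nt, c] <- ev$nuclei
          ploidy[idx:nt, c] <- ev$ploidy_c
          dna_rel[idx:nt, c] <- ev$dna_rel
          comp[idx:nt, c] <- ev$cells
          fission_frac[idx] <- fission_frac[idx] + fracs[c]
        },
        DAUGHTER_RELEASE = {
          released[c] <- TRUE
          release_time[c] <- times[idx]
          n_rel <- states[[c]]$committed
          cellsf[idx:nt, c] <- 2^n_rel
          comp[idx:nt, c] <- 2^n_rel
          dna_rel[idx:nt, c] <- 1
          nuclei[idx:nt, c] <- 1
          ploidy[idx:nt, c] <- 1
          # daughters carry 1/2^n of the mother's biomass each
          ii <- idx:nt
          dm_rel[ii, c] <- dm_rel[ii, c] / 2^n_rel
          vol_rel[ii, c] <- vol_rel[ii, c] / 2^n_rel
          rna_rel[ii, c] <- rna_rel[ii, c] / 2^n_rel
        })
      ev_i <- ev_i + 1L
    }
  }
  # starch integration on the culture level
  starch <- numeric(nt)
  starch[1] <- cfg$starch$initial
  for (i in seq_len(nt - 1L)) {
    starch[i + 1] <- starch_step(starch[i], dt, I_m[i], X_series[i],
                                 cfg$starch,
                                 dividing_fraction = fission_frac[i + 1])
  }

  cell_conc <- cfg$initial_cell_conc * as.vector(cellsf %*% fracs)
  # population means of per-cell quantities, weighted by cell counts
  wts <- sweep(cellsf, 2, fracs, `*`)
  wsum <- rowSums(wts)
  wmean <- function(m) rowSums(m * wts) / wsum
  # DNA as assayed: total DNA per counted cell (counters only register
  # released cells, so the population signal plateaus at 2^n x initial
  # until daughter release)
  dna_assay <- cfg$initial_DNA *
    as.vector((dna_rel * comp) %*% fracs) / as.vector(cellsf %*% fracs)
  traj <- data.frame(
    time_h = times,
    cell_conc_1e6_per_ml = cell_conc,
    dry_matter_ug_per_ml = X_series,
    mean_light = I_m,
    dna_pg_per_cell = dna_assay,
    rna_rel = wmean(rna_rel),
    volume_um3 = cfg$initial_cell_volume * wmean(vol_rel),
    starch_ug_per_ml = starch,
    nuclei = wmean(nuclei),
    ploidy_C = wmean(ploidy))

  events <- do.call(rbind, lapply(seq_len(nc), function(c) {
    log <- logs[[c]]
    if (!nrow(log)) return(NULL)
    cbind(cohort = n_targets[c], log)
  }))
  if (is.null(events)) events <- cbind(cohort = integer(0), new_event_log())

  cohorts <- data.frame(
    n_target = n_targets,
    fraction = as.numeric(fracs),
    committed = vapply(states, function(s) s$committed, integer(1)),
    steps_done = vapply(states, function(s) s$steps_done, integer(1)),
    released = released,
    release_time = release_time,
    daughters = 2^vapply(states, function(s) s$committed, integer(1)))

  structure(list(trajectory = traj, events = events, cohorts = cohorts,
                 config = cfg, truncated = truncated),
            class = "culture_trajectory")
}

#' @export
print.culture_trajectory <- function(x, ...) {
  cat(sprintf("Culture trajectory: %d samples over %g h, %d cohort(s)\n",
              nrow(x$trajectory), max(x$trajectory$time_h),
              nrow(x$cohorts)))
  print(x$cohorts)
  invisible(x)
}

#' Summary statistics of a simulated cycle
#'
#' `dna_fold()` is the fraction-weighted mean of the per-cohort maximal
#' per-cell DNA fold (each cohort reaches `2^n` before dividing);
#' `daughters_per_mother()` the fraction-weighted mean daughter number;
#' `final_dry_matter()` the culture dry matter at the end of the cycle
#' (daughter release); `starch_fold()` the final/initial net starch ratio.
#'
#' @param x A `culture_trajectory`.
#' @return A single number.
#' @export
dna_fold <- function(x) {
  stopifnot(inherits(x, "culture_trajectory"))
  sum(x$cohorts$fraction * 2^x$cohorts$committed)
}

#' @rdname dna_fold
#' @export
daughters_per_mother <- function(x) {
  stopifnot(inherits(x, "culture_trajectory"))
  sum(x$cohorts$fraction * x$cohorts$daughters)
}

#' @rdname dna_fold
#' @export
final_dry_matter <- function(x) {
  stopifnot(inherits(x, "culture_trajectory"))
  tr <- x$trajectory
  t_end <- if (all(x$cohorts$released)) max(x$cohorts$release_time)
           else max(tr$time_h)
  tr$dry_matter_ug_per_ml[which.min(abs(tr$time_h - t_end))]
}

#' @rdname dna_fold
#' @export
starch_fold <- function(x) {
  stopifnot(inherits(x, "culture_trajectory"))
  s <- x$trajectory$starch_ug_per_ml
  s[length(s)] / s[1]
}
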