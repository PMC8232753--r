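# Division and growth statistics: division number, doubling times,
# percent-of-control / fold-retardation (with the half-up 2-decimal rounding
# convention of the reference tables), and detectors for stepwise log2
# growth and DNA replication rounds.

#' Round half-up to a fixed number of decimals
#'
#' Presentation rounding used by the division/mass tables (0.005 rounds up,
#' unlike the banker's rounding of [round()]).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Division number: daughters per mother over one cycle
#'
#' @param N0,N1 Cell concentrations at the start and end of one division
#'   cycle (same units), both `> 0`.
#' @return `N1 / N0`.
#' @export
division_number <- function(N0, N1) {
  if (any(N0 <= 0) || any(N1 <= 0)) stop("cell counts must be positive")
  N1 / N0
}

#' Doubling time assuming exponential change
#'
#' `(t1 - t0) * ln 2 / ln(N1 / N0)`.
#'
#' @param t0,t1 Interval endpoints (h), `t1 > t0`.
#' @param N0,N1 Quantity at the endpoints, `N1 > N0 > 0`.
#' @return Doubling time (h).
#' @export
doubling_time <- function(t0, t1, N0, N1) {
  if (any(t1 <= t0)) stop("t1 must exceed t0")
  if (any(N0 <= 0)) stop("N0 must be positive")
  if (any(N1 <= N0)) stop("doubling time undefined: N1 must exceed N0")
  (t1 - t0) * log(2) / log(N1 / N0)
}

#' Percent of control
#'
#' `100 * x / control`, rounded half-up to 2 decimals (raw value in the
#' `"raw"` attribute).
#'
#' @param x Treated value.
#' @param control Control value, `> 0`.
#' @return Percentage, 2 decimals.
#' @export
percent_of_control <- function(x, control) {
  if (any(control <= 0)) stop("control must be positive")
  raw <- 100 * x / control
  structure(round_half_up(raw, 2), raw = raw)
}

#' Fold retardation relative to control
#'
#' `Td / Td_control`, rounded half-up to 2 decimals (raw value in the
#' `"raw"` attribute).
#'
#' @param Td Treated doubling time, `> 0`.
#' @param Td_control Control doubling time, `> 0`.
#' @return Fold retardation, 2 decimals.
#' @export
fold_retardation <- function(Td, Td_control) {
  if (any(Td <= 0) || any(Td_control <= 0)) {
    stop("doubling times must be positive")
  }
  raw <- Td / Td_control
  structure(round_half_up(raw, 2), raw = raw)
}

#' Mass multiplication factor and mass doubling time
#'
#' Optical-density analogues of [division_number()] and [doubling_time()]:
#' biomass growth assessed from OD750 readings.
#'
#' @param OD0,OD1 Optical densities at the interval endpoints, `> 0`.
#' @param t0,t1 Interval endpoints (h).
#' @return Factor (dimensionless) or doubling time (h).
#' @export
mass_multiplication_factor <- function(OD0, OD1) {
  if (any(OD0 <= 0) || any(OD1 <= 0)) stop("optical densities must be positive")
  OD1 / OD0
}

#' @rdname mass_multiplication_factor
#' @export
mass_doubling_time <- function(t0, t1, OD0, OD1) {
  doubling_time(t0, t1, OD0, OD1)
}

# Runs of near-zero slope in a smoothed log2 series.
# Returns a data frame of plateaus (start/end index, median level).
# A flat run observed over [t_i, t_j] is consistent with a plateau extending
# up to half a sampling interval beyond each end, so the effective span is
# (t_j - t_i) plus one sampling interval.
find_plateaus <- function(t, y, eps, tau_min) {
  dy <- diff(y) / diff(t)
  spacing <- stats::median(diff(t))
  flat <- abs(dy) < eps
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    i0 <- starts[j]; i1 <- ends[j] + 1L   # diff index k spans points k, k+1
    if (t[i1] - t[i0] + spacing >= tau_min - 1e-9) {
      out[[length(out) + 1L]] <- data.frame(
        start = i0, end = i1, level = stats::median(y[i0:i1]))
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      level = numeric(0)))
  }
  do.call(rbind, out)
}

smooth_log2 <- function(value, w) {
  y <- log2(value / value[1])
  if (w > 1 && length(y) >= w) {
    w_odd <- if (w %% 2 == 0) w + 1L else w
    y <- as.numeric(stats::runmed(y, w_odd, endrule = "median"))
  }
  y
}

#' Count growth steps in a stepwise-doubling time series
#'
#' Detects the number of completed biomass doublings in a (possibly noisy)
#' growth series. The series is converted to doublings
#' `y = log2(value / value[1])`, smoothed with a running median (window `w`
#' samples), and the step count is the nearest integer to `max(y)`.
#' Step-completion times are the first crossings of `y` above `k - delta`
#' for `k = 1..n`. Each crossing except the last must be followed by a
#' plateau (`|dy/dt| < eps` for at least `tau_min` hours); if not, the count
#' is returned with `low_confidence = TRUE`.
#'
#' @param time Sample times (h), ascending, length >= 8.
#' @param value Strictly positive measurements.
#' @param w Smoothing window (samples).
#' @param eps Plateau slope threshold (doublings per h).
#' @param tau_min Minimum plateau duration (h).
#' @param delta Crossing tolerance below the integer level (doublings).
#' @return List with `n` (integer step count), `step_times` (first-crossing
#'   times), and `low_confidence`.
#' @export
count_growth_steps <- function(time, value, w = 5, eps = 0.02,
                               tau_min = 1.5, delta = 0.1) {
  if (length(time) != length(value)) stop("time and value lengths differ")
  if (length(time) < 8L) stop("at least 8 samples are required")
  if (any(value <= 0)) stop("values must be strictly positive")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be ascending")
  y <- smooth_log2(value, w)
  n <- as.integer(round(max(y)))
  if (n <= 0L) {
    return(list(n = 0L, step_times = numeric(0), low_confidence = FALSE))
  }
  step_times <- vapply(seq_len(n), function(k) {
    i <- which(y >= k - delta)[1]
    if (is.na(i)) NA_real_ else time[i]
  }, numeric(1))
  plateaus <- find_plateaus(time, y, eps, tau_min)
  low_conf <- FALSE
  if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      tk <- step_times[k]
      ok <- any(plateaus$level > k - 0.5 & plateaus$level < k + 0.5 &
                  time[plateaus$end] >= tk)
      if (!ok) low_conf <- TRUE
    }
  }
  list(n = n, step_times = step_times, low_confidence = low_conf)
}

#' Estimate DNA replication rounds from a per-cell DNA series
#'
#' Detects the plateaus of a (possibly noisy) DNA-per-cell series and
#' returns the nearest integer to `log2(final / initial)` where `initial` is
#' the median of the first detected plateau and `final` the median of the
#' highest one (per-cell DNA falls back to the initial amount when daughters
#' are released, so the maximal plateau is the pre-division level).
#'
#' The default smoothing window is narrower than for growth steps: the
#' pre-division DNA plateau of a single-round cycle is short, and a wide
#' running median would erase it.
#'
#' @inheritParams count_growth_steps
#' @return List with `rounds` (integer), `low_confidence`.
#' @export
estimate_replication_rounds <- function(time, value, w = 3, eps = 0.02,
                                        tau_min = 1.5) {
  if (length(time) != length(value)) stop("time and value lengths differ")
  if (length(time) < 8L) stop("at least 8 samples are required")
  if (any(value <= 0)) stop("values must be strictly positive")
  y <- smooth_log2(value, w)
  plateaus <- find_plateaus(time, y, eps, tau_min)
  if (nrow(plateaus) == 0L) {
    # no plateau long enough: fall back to series extremes
    return(list(rounds = as.integer(round(max(y) - y[1])),
                low_confidence = TRUE))
  }
  first <- plateaus$level[1]
  final <- max(plateaus$level)
  if (max(y) > final + 0.5) {
    # the top plateau was too short or broken by noise; fall back to the
    # smoothed maximum
    return(list(rounds = as.integer(round(max(y) - first)),
                low_confidence = TRUE))
  }
  list(rounds = as.integer(round(final - first)), low_confidence = FALSE)
}

#' Division and mass statistics of a simulated or measured cycle
#'
#' Convenience wrapper computing the table statistics from a tidy trajectory
#' (columns `time_h`, `cell_conc_1e6_per_ml`, and a biomass column) over the
#' interval `[t0, t1]` (defaults: whole series). With a control, also
#' percent-of-control and fold-retardation columns.
#'
#' @param series Data frame as written by [simulate_culture()] /
#'   [write_trajectory_csv()].
#' @param control Optional control series of the same layout.
#' @param t0,t1 Interval endpoints (default first/last sample).
#' @param mass_column Column holding the biomass/OD proxy.
#' @return A one-row data frame of statistics.
#' @export
division_stats <- function(series, control = NULL, t0 = NULL, t1 = NULL,
                           mass_column = "dry_matter_ug_per_ml") {
  need <- c("time_h", "cell_conc_1e6_per_ml", mass_column)
  miss <- setdiff(need, names(series))
  if (length(miss)) stop("missing required columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(t0)) t0 <- series$time_h[1]
  if (is.null(t1)) t1 <- series$time_h[nrow(series)]
  at <- function(tt, col) {
    series[[col]][which.min(abs(series$time_h - tt))]
  }
  N0 <- at(t0, "cell_conc_1e6_per_ml"); N1 <- at(t1, "cell_conc_1e6_per_ml")
  M0 <- at(t0, mass_column); M1 <- at(t1, mass_column)
  out <- data.frame(
    division_number = division_number(N0, N1),
    doubling_time_h = if (N1 > N0) doubling_time(t0, t1, N0, N1) else NA_real_,
    mass_multiplication_factor = mass_multiplication_factor(M0, M1),
    mass_doubling_time_h = if (M1 > M0) mass_doubling_time(t0, t1, M0, M1)
                           else NA_real_)
  if (!is.null(control)) {
    ctrl <- division_stats(control, t0 = t0, t1 = t1,
                           mass_column = mass_column)
    out$percent_of_control <- as.numeric(
      percent_of_control(out$division_number, ctrl$division_number))
    out$fold_retardation <- as.numeric(
      fold_retardation(out$doubling_time_h, ctrl$doubling_time_h))
    out$mass_percent_of_control <- as.numeric(
      percent_of_control(out$mass_multiplication_factor,
                         ctrl$mass_multiplication_factor))
    out$mass_fold_retardation <- as.numeric(
      fold_retardation(out$mass_doubling_time_h, ctrl$mass_doubling_time_h))
  }
  out
}
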