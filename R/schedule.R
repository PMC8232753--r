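# Pattern-lawful scheduling of reproductive events.
#
# A reproductive sequence is one round of pS -> S (DNA replication) -> G2 ->
# M (nuclear division) -> G3 -> C (protoplast fission). The four
# multiple-fission patterns differ only in how the n overlapping sequences
# interleave these events; the scheduler turns a vector of commitment-point
# times into a complete event log for one mother cell.

event_levels <- function() {
  c("CP", "S_START", "S_END", "M", "FISSION", "DAUGHTER_RELEASE")
}

new_event_log <- function(time = numeric(0), event = character(0),
                          seq = integer(0), nuclei = integer(0),
                          ploidy_c = numeric(0), cells = integer(0),
                          dna_rel = numeric(0)) {
  structure(data.frame(time = time, event = event, seq = seq,
                       nuclei = nuclei, ploidy_c = ploidy_c, cells = cells,
                       dna_rel = dna_rel, stringsAsFactors = FALSE),
            class = c("event_log", "data.frame"))
}

# stable sort by time with CP < S < M < FISSION < RELEASE on ties
sort_event_log <- function(log) {
  pri <- match(log$event, event_levels())
  log[order(log$time, pri), , drop = FALSE]
}

#' Schedule the reproductive events of one mother cell
#'
#' Given the pattern, the commitment-point times of the n initiated
#' reproductive sequences and the phase durations, returns the complete
#' event log: replication rounds (`S_START`/`S_END`), nuclear divisions
#' (`M`), protoplast fissions (`FISSION`) and the final `DAUGHTER_RELEASE`.
#' Each row also carries the cell state immediately after the event:
#' nuclei per cell, ploidy per nucleus (C-value multiples), protoplast
#' compartments per mother (`cells`) and DNA per compartment relative to the
#' unreplicated amount (`dna_rel`).
#'
#' Replication-round timing: the first round starts `pS` after the first
#' commitment point; in patterns whose rounds run consecutively
#' (Parachlorella, Haematococcus, Scenedesmus) each later round starts
#' `inter_S_gap` after the previous round ends, but never before its own
#' commitment point. In the clustered pattern no replication occurs before
#' the final commitment point.
#'
#' @param pattern One of [pattern_types()].
#' @param cp_times Ascending commitment-point times (h); length n, n >= 0.
#'   `n = 0` yields an empty log (an uncommitted cell does not divide).
#' @param phase A [phase_durations()].
#' @return An `event_log` data frame ordered by time (ties broken
#'   CP < S < M < FISSION < RELEASE).
#' @examples
#' schedule_reproduction("HAEMATOCOCCUS", c(3, 6), phase_durations())
#' @export
schedule_reproduction <- function(pattern, cp_times, phase = phase_durations()) {
  pattern <- match.arg(pattern, pattern_types())
  stopifnot(inherits(phase, "phase_durations"))
  n <- length(cp_times)
  if (n == 0L) return(new_event_log())
  if (is.unsorted(cp_times, strictly = FALSE)) {
    stop("commitment-point times must be ascending")
  }
  p <- phase
  rows <- list()
  add <- function(time, event, seq, nuclei, ploidy, cells, dna) {
    rows[[length(rows) + 1L]] <<- data.frame(
      time = time, event = event, seq = seq, nuclei = nuclei,
      ploidy_c = ploidy, cells = cells, dna_rel = dna,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(n)) {
    add(cp_times[k], "CP", k, NA_integer_, NA_real_, NA_integer_, NA_real_)
  }

  # consecutive replication rounds (first gated by pS, later by the gap)
  chain_S <- function() {
    s_start <- numeric(n); s_end <- numeric(n)
    s_start[1] <- cp_times[1] + p$pS
    s_end[1] <- s_start[1] + p$S
    if (n > 1) for (k in 2:n) {
      s_start[k] <- max(cp_times[k], s_end[k - 1] + p$inter_S_gap)
      s_end[k] <- s_start[k] + p$S
    }
    list(start = s_start, end = s_end)
  }

  if (pattern == "PARACHLORELLA") {
    s <- chain_S()
    for (k in seq_len(n)) {   # uni-nuclear polyploidization: ploidy 2^k
      add(s$start[k], "S_START", k, 1L, 2^(k - 1), 1L, 2^(k - 1))
      add(s$end[k],   "S_END",   k, 1L, 2^k,       1L, 2^k)
    }
    t0 <- s$end[n] + p$G2
    for (k in seq_len(n)) {   # M immediately followed by fission, G3 = 0
      tm <- t0 + (k - 1) * (p$M + p$C)
      add(tm, "M", k, 2L, 2^(n - k), 2^(k - 1), 2^(n - k + 1))
      add(tm + p$M, "FISSION", k, 1L, 2^(n - k), 2^k, 2^(n - k))
    }
    add(t0 + (n - 1) * (p$M + p$C) + p$M + p$C, "DAUGHTER_RELEASE", n,
        1L, 1, 2^n, 1)
  } else if (pattern == "HAEMATOCOCCUS") {
    s <- chain_S()
    for (k in seq_len(n)) {
      add(s$start[k], "S_START", k, 1L, 2^(k - 1), 1L, 2^(k - 1))
      add(s$end[k],   "S_END",   k, 1L, 2^k,       1L, 2^k)
    }
    t0 <- s$end[n] + p$G2
    for (k in seq_len(n)) {   # all nuclear divisions: polynuclear stage
      add(t0 + (k - 1) * p$M, "M", k, 2^k, 2^(n - k), 1L, 2^n)
    }
    tf <- t0 + n * p$M + p$G3
    for (k in seq_len(n)) {
      add(tf + (k - 1) * p$C, "FISSION", k, 2^(n - k), 1, 2^k, 2^(n - k))
    }
    add(tf + n * p$C, "DAUGHTER_RELEASE", n, 1L, 1, 2^n, 1)
  } else if (pattern == "CLUSTERED_CHLAMYDOMONAS") {
    t0 <- cp_times[n] + p$pS   # nothing before the final CP
    tcur <- t0
    for (k in seq_len(n)) {    # rapid S -> M alternation
      add(tcur, "S_START", k, 2^(k - 1), 1, 1L, 2^(k - 1))
      add(tcur + p$S, "S_END", k, 2^(k - 1), 2, 1L, 2^k)
      add(tcur + p$S + p$G2, "M", k, 2^k, 1, 1L, 2^k)
      tcur <- tcur + p$S + p$G2 + p$M
    }
    tf <- tcur + p$G3
    for (k in seq_len(n)) {
      add(tf + (k - 1) * p$C, "FISSION", k, 2^(n - k), 1, 2^k, 2^(n - k))
    }
    add(tf + n * p$C, "DAUGHTER_RELEASE", n, 1L, 1, 2^n, 1)
  } else { # CONSECUTIVE_SCENEDESMUS
    s_start <- numeric(n); s_end <- numeric(n); m_t <- numeric(n)
    s_start[1] <- cp_times[1] + p$pS
    s_end[1] <- s_start[1] + p$S
    m_t[1] <- s_end[1] + p$G2
    if (n > 1) for (k in 2:n) {
      s_start[k] <- max(cp_times[k] + p$pS, s_end[k - 1] + p$inter_S_gap)
      s_end[k] <- s_start[k] + p$S
      m_t[k] <- max(s_end[k] + p$G2, m_t[k - 1] + p$M)
    }
    for (k in seq_len(n)) {   # nuclei 2, 4, ..., 2^n before any fission
      add(s_start[k], "S_START", k, 2^(k - 1), 1, 1L, 2^(k - 1))
      add(s_end[k],   "S_END",   k, 2^(k - 1), 2, 1L, 2^k)
      add(m_t[k],     "M",       k, 2^k,       1, 1L, 2^k)
    }
    tf <- m_t[n] + p$M + p$G3
    for (k in seq_len(n)) {
      add(tf + (k - 1) * p$C, "FISSION", k, 2^(n - k), 1, 2^k, 2^(n - k))
    }
    add(tf + n * p$C, "DAUGHTER_RELEASE", n, 1L, 1, 2^n, 1)
  }
  log <- do.call(rbind, rows)
  class(log) <- c("event_log", "data.frame")
  sort_event_log(log)
}

#' Number of daughter cells released after n reproductive sequences
#'
#' One mother completing n sequences releases `2^n` daughters.
#'
#' @param n Nonnegative integer (vectorised).
#' @return `2^n`.
#' @export
daughters_released <- function(n) {
  if (any(n < 0) || any(n != floor(n))) {
    stop("n must be a nonnegative integer")
  }
  2^n
}

#' Population-mean DNA fold increase over one cycle
#'
#' For cohort fractions mapping n (sequences completed) to the fraction of
#' mothers, the population-mean fold increase of per-cell DNA is
#' `sum(fraction(n) * 2^n)`.
#'
#' @param cohort_fractions Named numeric vector (names = n); must sum to 1.
#' @return The fraction-weighted mean DNA fold.
#' @examples
#' dna_fold_increase(c("4" = 1))              # 16
#' dna_fold_increase(c("3" = 0.5, "4" = 0.5)) # 12
#' @export
dna_fold_increase <- function(cohort_fractions) {
  if (any(cohort_fractions < 0)) stop("fractions must be nonnegative")
  if (abs(sum(cohort_fractions) - 1) > 1e-9) {
    stop("cohort fractions must sum to 1")
  }
  ns <- as.numeric(names(cohort_fractions))
  if (any(is.na(ns))) stop("cohort_fractions must be named by n")
  sum(cohort_fractions * 2^ns)
}
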