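# Division/doubling statistics and the step / replication-round detectors.

test_that("division number and doubling time follow the exponential
           identities", {
  expect_equal(division_number(1, 8), 8)
  expect_equal(division_number(1, 1), 1)
  expect_error(division_number(0, 4), "positive")
  expect_equal(doubling_time(0, 24, 1, 8), 8)
  expect_equal(doubling_time(0, 24, 1, 2), 24)
  # round-trip: sampling any exact exponential recovers its doubling time
  tau <- c(3.7, 9.98, 22.8)
  for (tt in tau) {
    N <- function(t) 1.3 * 2^(t / tt)
    expect_equal(doubling_time(2, 17, N(2), N(17)), tt, tolerance = 1e-12)
  }
  expect_error(doubling_time(0, 24, 2, 2), "must exceed")
  expect_error(doubling_time(5, 5, 1, 2), "exceed")
})

test_that("mass statistics mirror the count statistics on OD values", {
  expect_equal(mass_multiplication_factor(1, 4.33), 4.33)
  expect_equal(mass_doubling_time(0, 24, 0.25, 1), 12)
  expect_error(mass_doubling_time(0, 24, 0.25, 0.25), "exceed")
})

test_that("percent of control and fold retardation reproduce the reference
           table cells exactly at two decimals", {
  # each pair recomputes from other printed cells of the same table
  expect_identical(as.numeric(percent_of_control(4.77, 6.96)), 68.53)
  expect_identical(as.numeric(percent_of_control(1.12, 7.44)), 15.05)
  expect_identical(as.numeric(fold_retardation(22.80, 9.98)), 2.28)
  expect_identical(as.numeric(fold_retardation(46.13, 9.05)), 5.10)
  expect_identical(as.numeric(fold_retardation(306.28, 13.65)), 22.44)
  expect_identical(as.numeric(fold_retardation(49.09, 10.60)), 4.63)
  expect_identical(as.numeric(percent_of_control(3, 3)), 100)
  expect_identical(as.numeric(fold_retardation(7, 7)), 1)
  expect_error(percent_of_control(1, 0), "positive")
  expect_error(fold_retardation(-1, 2), "positive")
})

test_that("half-up rounding differs from banker's rounding where it must", {
  expect_identical(round_half_up(0.125, 2), 0.13)
  expect_identical(round_half_up(-0.125, 2), -0.13)
  expect_identical(round_half_up(2.28499, 2), 2.28)
})

test_that("growth-step counting is exact on noiseless engine output", {
  tr <- single_cohort_traj(2)
  traj <- tr$trajectory
  idx <- seq(1, nrow(traj), by = 20)  # 1-h sampling
  res <- count_growth_steps(traj$time_h[idx], traj$volume_um3[idx])
  expect_identical(res$n, 2L)
  # crossing times sit near the engine's step completions
  cp <- tr$events$time[tr$events$event == "CP"]
  expect_true(all(abs(res$step_times - cp) <= 1.5))
})

test_that("a constant series has zero steps and zero replication rounds", {
  t <- 0:23
  v <- rep(5, 24)
  expect_identical(count_growth_steps(t, v)$n, 0L)
  expect_identical(estimate_replication_rounds(t, v)$rounds, 0L)
})

test_that("step counting is scale invariant", {
  tr <- single_cohort_traj(3)
  traj <- tr$trajectory
  idx <- seq(1, nrow(traj), by = 20)
  base <- count_growth_steps(traj$time_h[idx], traj$volume_um3[idx])
  for (c in c(1e-3, 7, 1e4)) {
    scaled <- count_growth_steps(traj$time_h[idx], c * traj$volume_um3[idx])
    expect_identical(scaled$n, base$n)
  }
})

test_that("replication rounds are exact on noiseless DNA series", {
  for (n in c(2, 4)) {
    tr <- single_cohort_traj(n)
    traj <- tr$trajectory
    idx <- seq(1, nrow(traj), by = 20)
    res <- estimate_replication_rounds(traj$time_h[idx],
                                       traj$dna_pg_per_cell[idx])
    expect_identical(res$rounds, as.integer(n))
  }
})

test_that("detectors reject degenerate input", {
  expect_error(count_growth_steps(1:5, rep(1, 5)), "8 samples")
  expect_error(count_growth_steps(1:10, c(rep(1, 9), -1)), "positive")
  expect_error(count_growth_steps(1:10, rep(1, 9)), "lengths differ")
  expect_error(estimate_replication_rounds(1:10, c(rep(1, 9), 0)),
               "positive")
})

test_that("division statistics agree with the engine's cohort summary", {
  tr <- single_cohort_traj(3)
  stats <- division_stats(tr$trajectory)
  expect_equal(stats$division_number, 8)
  expect_equal(stats$mass_multiplication_factor, 8)
  # against a control: identical series give 100% and fold 1
  both <- division_stats(tr$trajectory, control = tr$trajectory)
  expect_identical(both$percent_of_control, 100)
  expect_identical(both$fold_retardation, 1)
  expect_error(division_stats(tr$trajectory[, 1:2]), "missing required")
})
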