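# Culture engine: growth kinetics, light feedback, conservation laws and
# the printed end-of-cycle anchors.

test_that("growth rate follows a Monod light response with retardation", {
  g <- growth_params()
  expect_equal(growth_rate(0, g), 0)
  expect_equal(growth_rate(1e9, g), g$mu_max, tolerance = 1e-6)
  expect_equal(growth_rate(g$K_I, g), g$mu_max / 2)
  expect_gt(growth_rate(360, g), growth_rate(80, g))
  expect_equal(growth_rate(200, g, rho_growth = 2),
               growth_rate(200, g) / 2)
  expect_error(growth_rate(-1, g), "nonnegative")
  expect_error(growth_rate(100, g, rho_growth = 0.5), ">= 1")
})

test_that("a growth step at constant rate completes after ln2/rate hours", {
  r <- 0.2
  dt <- 0.01
  st <- NULL
  t <- 0
  repeat {
    st <- advance_growth(st, dt, r, idle_length = 2)
    t <- t + dt
    if (st$cp_fired) break
  }
  expect_equal(t, log(2) / r, tolerance = dt / (log(2) / r) + 1e-9)
  # proxies exactly doubled at completion
  expect_identical(st$volume, 2)
  expect_identical(st$dry_matter, 2)
  # an idle interval follows before the next step
  st2 <- advance_growth(st, dt, r, idle_length = 2)
  expect_equal(st2$mode, "idle")
})

test_that("growth is frozen in the dark", {
  st <- NULL
  for (i in 1:50) st <- advance_growth(st, 0.1, 0.3, light_on = FALSE)
  expect_equal(st$volume, 1)
  expect_equal(st$steps_done, 0L)
})

test_that("the highest-light cycle gives 16-fold DNA, 16 daughters and
           dry matter 100 -> 1600", {
  tr <- cached_traj("fig5_500")
  expect_identical(dna_fold(tr), 16)
  expect_identical(daughters_per_mother(tr), 16)
  expect_identical(final_dry_matter(tr), 1600)
  # per-cell DNA climbs stepwise from 0.1 to 1.6 pg before division
  expect_equal(max(tr$trajectory$dna_pg_per_cell), 1.6, tolerance = 1e-9)
  expect_equal(tr$trajectory$dna_pg_per_cell[1], 0.1)
  expect_false(tr$truncated)
})

test_that("the lowest-light cycle gives 4-fold DNA and dry matter 400", {
  tr <- cached_traj("fig5_110")
  expect_identical(dna_fold(tr), 4)
  expect_identical(daughters_per_mother(tr), 4)
  expect_identical(final_dry_matter(tr), 400)
})

test_that("the mixed 250 uE cohort yields a population-mean DNA fold of 12", {
  tr <- cached_traj("fig5_250")
  expect_identical(dna_fold(tr), 12)
  expect_identical(daughters_per_mother(tr), 12)
})

test_that("biomass proxies double exactly per completed step and daughters
           carry 1/2^n of the mother biomass", {
  tr <- cached_traj("fig5_500")
  traj <- tr$trajectory
  rel <- tr$cohorts$release_time[1]
  before <- traj[traj$time_h < rel, ]
  # mother volume peaks at 2^4 x initial; RNA is capped at three doublings
  expect_equal(max(before$volume_um3) / before$volume_um3[1], 16,
               tolerance = 1e-9)
  expect_equal(max(before$rna_rel), 8, tolerance = 1e-9)
  after <- traj[traj$time_h >= rel, ]
  expect_equal(after$volume_um3[1] / before$volume_um3[1], 1,
               tolerance = 1e-9)
})

test_that("DNA is conserved at every fission and release", {
  for (p in c("fig5_500", "fig5_110")) {
    tr <- cached_traj(p)
    ev <- tr$events
    fis <- ev[ev$event %in% c("FISSION", "DAUGHTER_RELEASE"), ]
    n <- max(ev$seq)
    # total DNA per mother is 2^n x initial throughout division
    expect_equal(fis$cells * fis$dna_rel, rep(2^n, nrow(fis)),
                 tolerance = 1e-12)
  }
})

test_that("no DNA synthesis occurs outside S phases", {
  tr <- cached_traj("fig5_500")
  traj <- tr$trajectory
  ev <- tr$events
  s_windows <- cbind(ev$time[ev$event == "S_START"],
                     ev$time[ev$event == "S_END"])
  rel <- tr$cohorts$release_time[1]
  rising <- which(diff(traj$dna_pg_per_cell) > 1e-12)
  t_rising <- traj$time_h[rising]
  in_s <- vapply(t_rising, function(tt) {
    any(tt >= s_windows[, 1] - 1e-9 & tt <= s_windows[, 2] + 1e-9)
  }, logical(1))
  expect_true(all(in_s | t_rising >= rel))
})

test_that("dark intervals freeze biomass and commitments but committed
           sequences still complete", {
  tr <- cached_traj("fig5_500")
  traj <- tr$trajectory
  dark <- traj$time_h >= 18 & traj$time_h < 25
  expect_equal(diff(range(traj$dry_matter_ug_per_ml[dark])), 0)
  expect_true(all(traj$mean_light[dark] == 0))
  # fissions and release fire inside the dark period
  ev <- tr$events
  expect_true(any(ev$event == "FISSION" & ev$time >= 18))
  expect_true(all(tr$cohorts$released))
})

test_that("mean light decreases while the culture grows in the light", {
  tr <- cached_traj("fig5_500")
  traj <- tr$trajectory
  lit <- traj$time_h < 18
  expect_true(all(diff(traj$mean_light[lit]) <= 1e-12))
  expect_equal(traj$mean_light[1], 360, tolerance = 0.01)
})

test_that("more light never means fewer completed growth steps", {
  steps <- vapply(c(110, 250, 500), function(I) {
    cfg <- preset("fig5_500", I_i = I)   # same cohort target n = 4
    sum(simulate_culture(cfg)$cohorts$steps_done)
  }, numeric(1))
  expect_true(all(diff(steps) >= 0))
})

test_that("a too-short horizon truncates with a warning and a flag", {
  cfg <- preset("fig5_500", horizon = 15)
  expect_warning(tr <- simulate_culture(cfg), "truncat")
  expect_true(tr$truncated)
})

test_that("an uncommitted cohort neither grows nor divides", {
  tr <- simulate_culture(preset("fig5_110", cohort_fractions = c("0" = 1)))
  expect_equal(nrow(tr$events), 0L)
  expect_identical(daughters_per_mother(tr), 1)
  expect_identical(dna_fold(tr), 1)
  expect_equal(diff(range(tr$trajectory$dry_matter_ug_per_ml)), 0)
  expect_equal(unique(tr$trajectory$cell_conc_1e6_per_ml), 1)
})

test_that("cell concentration multiplies by 2^n only at daughter release", {
  tr <- cached_traj("fig5_110")
  traj <- tr$trajectory
  rel <- tr$cohorts$release_time[1]
  expect_equal(unique(traj$cell_conc_1e6_per_ml[traj$time_h < rel]), 1)
  expect_equal(unique(traj$cell_conc_1e6_per_ml[traj$time_h >= rel]), 4)
})

test_that("darkening at first fission yields the same daughters with
           biomass frozen from darkening onward", {
  ctrl <- cached_traj("fig5_250")
  t_fission <- min(ctrl$events$time[ctrl$events$event == "FISSION"])
  dark <- simulate_culture(preset("fig5_250",
                                  light_schedule = c(t_fission, 48)))
  expect_identical(daughters_per_mother(dark), daughters_per_mother(ctrl))
  after <- dark$trajectory$time_h >= t_fission
  expect_equal(diff(range(dark$trajectory$dry_matter_ug_per_ml[after])), 0)
})

test_that("deuterium retardation slows growth without changing the
           daughter count law", {
  slow <- simulate_culture(preset("d2o_70"))
  expect_true(all(slow$cohorts$released))
  expect_identical(daughters_per_mother(slow), 4)
  fast_cp <- simulate_culture(preset("d2o_70",
    retardation = c(rho_growth = 1, rho_division = 1)))$cohorts
  expect_lt(fast_cp$release_time[1], slow$cohorts$release_time[1])
})
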