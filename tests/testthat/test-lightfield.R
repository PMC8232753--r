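# Mean-light formula, bisection inversion, and attenuation calibration.

test_that("mean light intensity matches the closed form and its limits", {
  # frozen oracle values: 250/ln 2 and 55/ln 2
  expect_equal(mean_light_intensity(500, 250), 360.6738, tolerance = 1e-6)
  expect_equal(mean_light_intensity(250, 125), 180.3369, tolerance = 1e-6)
  expect_equal(mean_light_intensity(110, 55), 79.34823, tolerance = 1e-6)
  # continuity limit I_t -> I_i
  for (I in c(0.5, 1, 110, 500)) {
    expect_identical(mean_light_intensity(I, I), I)
    expect_equal(mean_light_intensity(I, I * (1 - 1e-12)), I)
  }
})

test_that("mean light intensity rejects impossible inputs", {
  expect_error(mean_light_intensity(500, 501), "cannot exceed")
  expect_error(mean_light_intensity(-1, 0.5), "positive")
  expect_error(mean_light_intensity(500, 0), "positive")
})

test_that("mean intensity lies strictly between transmitted and incident and
           is increasing in the transmitted intensity", {
  for (I_i in c(110, 250, 500)) {
    I_t <- I_i * seq(0.05, 0.95, by = 0.05)
    I_m <- mean_light_intensity(rep(I_i, length(I_t)), I_t)
    expect_true(all(I_m > I_t) && all(I_m < I_i))
    expect_true(all(diff(I_m) > 0))
  }
})

test_that("bisection inversion round-trips the mean intensity", {
  grid <- expand.grid(I_i = c(110, 250, 500), frac = c(0.1, 0.32, 0.72, 0.9))
  for (i in seq_len(nrow(grid))) {
    I_i <- grid$I_i[i]
    I_m <- grid$frac[i] * I_i
    I_t <- invert_mean_light(I_i, I_m)
    expect_equal(mean_light_intensity(I_i, I_t), I_m, tolerance = 1e-9)
  }
  expect_error(invert_mean_light(500, 600), "cannot exceed")
})

test_that("initial anchors imply a transmitted fraction of about one half", {
  anchors <- light_anchors()
  init <- anchors[anchors$dry_matter == 100, ]
  frac <- invert_mean_light(init$incident, init$mean) / init$incident
  expect_true(all(abs(frac - 0.5) < 0.02))
})

test_that("calibration recovers known parameters from noiseless anchors", {
  true <- attenuation_model(c1 = 0.009, c2 = 0.002)
  X <- c(50, 100, 400, 900, 1600)
  I_i <- rep(500, length(X))
  I_m <- mean_light_intensity(I_i, transmitted_intensity(I_i, X, true))
  fit <- calibrate_attenuation(
    data.frame(incident = I_i, mean = I_m, dry_matter = X))
  expect_equal(fit$c1, true$c1, tolerance = 1e-6)
  expect_equal(fit$c2, true$c2, tolerance = 1e-6)
})

test_that("calibration requires at least two distinct anchors", {
  one <- data.frame(incident = 500, mean = 360, dry_matter = 100)
  expect_error(calibrate_attenuation(one), "two anchors")
  dup <- rbind(one, one)
  expect_error(calibrate_attenuation(dup), "two anchors")
})

test_that("the default model reproduces all six endpoint anchors within 5%", {
  model <- default_attenuation_model()
  anchors <- light_anchors()
  pred <- mean_light_intensity(
    anchors$incident,
    transmitted_intensity(anchors$incident, anchors$dry_matter, model))
  expect_true(all(abs(pred / anchors$mean - 1) < 0.05))
  # transmitted fraction ~1/2 at the cycle-start density, optical depth ~2.9
  # at the highest final density
  expect_equal(exp(-optical_depth(100, model)), 0.5, tolerance = 0.02)
  expect_equal(optical_depth(1600, model), 2.9, tolerance = 0.05)
})

test_that("mean light trajectory is antitone in dry matter", {
  model <- default_attenuation_model()
  X <- seq(100, 1600, length.out = 40)
  I_m <- mean_light_trajectory(500, X, model)
  expect_true(all(diff(I_m) < 0))
  expect_equal(I_m[1], 360, tolerance = 0.01)
  expect_equal(I_m[40], 160, tolerance = 0.05)
  # constant series -> constant output; empty -> empty
  expect_equal(diff(range(mean_light_trajectory(500, rep(300, 5), model))), 0)
  expect_identical(mean_light_trajectory(500, numeric(0), model), numeric(0))
  expect_error(mean_light_trajectory(500, c(100, -5), model), "index 2")
})

test_that("no biomass means no attenuation", {
  model <- default_attenuation_model()
  expect_equal(transmitted_intensity(500, 0, model), 500)
  expect_error(transmitted_intensity(500, -1, model), "nonnegative")
})

test_that("attenuation model serialises losslessly", {
  model <- default_attenuation_model()
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_attenuation_model(model, path)
  back <- read_attenuation_model(path)
  X <- c(0, 100, 700, 1600)
  expect_equal(optical_depth(X, back), optical_depth(X, model),
               tolerance = 1e-12)
})
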