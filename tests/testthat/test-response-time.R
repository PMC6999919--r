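test_that("sensorimotor model is anchored to the 30-degree swing delay at 1 kg", {
  fits <- swing_fits_baseline()
  smd <- build_sensorimotor_model(fits)
  expect_equal(smd$exponent, 0.21)
  expect_equal(sensorimotor_delay(smd, 1), smd$coefficient)
  expect_equal(sensorimotor_delay(smd, 100) / sensorimotor_delay(smd, 1),
               100^0.21)
  # the anchored coefficient is the fitted 30-degree inertial delay at 1 kg:
  # close to 5.8 ms * sqrt(30) from the square-root magnitude law
  expect_close(smd$coefficient, 0.0058 * sqrt(30), rel = 0.05)
  expect_error(build_sensorimotor_model(fits, anchor_magnitude = 90),
               "outside")
  # config override wins
  cfg <- analysis_config(smd_coefficient = 0.02)
  expect_equal(build_sensorimotor_model(fits, config = cfg)$coefficient, 0.02)
})

test_that("swing and posture anchors imply the same sensorimotor coefficient within 10%", {
  smd_s <- build_sensorimotor_model(swing_fits_baseline())
  smd_p <- build_sensorimotor_model(posture_fits_baseline())
  expect_lt(abs(smd_s$coefficient - smd_p$coefficient) / smd_s$coefficient,
            0.10)
})

test_that("crossover magnitude: anchor identity, monotone decrease, range guard", {
  fits <- swing_fits_baseline()
  smd <- build_sensorimotor_model(fits)
  expect_equal(crossover_magnitude(fits, 1, smd), 30, tolerance = 1e-9)
  masses <- mass_grid()
  mags <- crossover_magnitude(fits, masses, smd, extrapolate = TRUE)
  expect_true(all(diff(mags) < 0))
  # a 5 g animal's crossover lies beyond the simulated 60-degree maximum
  expect_error(crossover_magnitude(fits, 0.005, smd), "extrapolate")
  expect_gt(crossover_magnitude(fits, 0.005, smd, extrapolate = TRUE), 60)
})

test_that("crossover laws scale near M^-0.14 and are algebraically consistent", {
  fits <- swing_fits_baseline()
  smd <- build_sensorimotor_model(fits)
  law <- fit_crossover_law(fits, smd)
  expect_equal(law$coefficient, 30, tolerance = 0.01)
  b <- average_exponent(fits)
  p <- coefficient_magnitude_law(fits)$exponent
  # exact algebra of the power-law construction ...
  expect_equal(law$exponent, (0.21 - b) / p, tolerance = 1e-6)
  # ... and the sqrt-magnitude approximation 2 (0.21 - b)
  expect_equal(law$exponent, 2 * (0.21 - b), tolerance = 0.01)

  plaw <- fit_crossover_law(posture_fits_baseline())
  expect_equal(plaw$coefficient, 0.21, tolerance = 0.01)
  # near-linear (not exactly unit-slope) coefficient growth perturbs the
  # identity only slightly
  expect_lt(abs(plaw$exponent -
                  (0.21 - average_exponent(posture_fits_baseline()))), 0.01)
})

test_that("available movement times follow their laws", {
  expect_equal(available_movement_time(1, "sprint_swing"), 0.148)
  expect_equal(available_movement_time(1000, "sprint_swing") /
                 available_movement_time(1, "sprint_swing"), 1000^0.13)
  expect_equal(available_movement_time(1, "fall"),
               fall_time(0.162, 9.81))
  expect_equal(available_movement_time(1, "pendulum_period"),
               pendulum_period(0.162, 9.81))
  expect_error(available_movement_time(1, "gallop"), "arg")
  expect_error(available_movement_time(-2, "fall"), "positive")
})

test_that("relative response time blends the two delays against sprint swing duration", {
  fits <- swing_fits_baseline()
  smd <- build_sensorimotor_model(fits)
  rrt <- relative_response_time(fits, smd)
  # at 1 kg the inertial and sensorimotor components are equal by the anchor
  at1 <- relative_response_time(fits, smd, masses = c(0.99, 1, 1.01))
  row1 <- at1[at1$mass_kg == 1, ]
  expect_equal(row1$inertial_s, row1$sensorimotor_s, tolerance = 1e-9)
  expect_equal(row1$response_s, 2 * sensorimotor_delay(smd, 1),
               tolerance = 1e-9)
  expect_equal(rrt$relative, rrt$response_s / rrt$available_s)

  law <- attr(rrt, "law")
  # the fitted exponent sits near the equal-weight blend of the two delay
  # exponents minus the sprint-duration exponent
  b <- average_exponent(fits)
  expect_lt(abs(law$exponent - ((0.21 + b) / 2 - 0.13)), 0.005)
})

test_that("torque sensitivity at factor 1 reproduces the baseline exactly", {
  cfg <- analysis_config(swing_magnitudes = c(5, 40))
  ts <- torque_sensitivity(swing_laws(), "swing", factors = 1, config = cfg)
  base <- average_exponent(
    fit_delay_scaling(delay_surface_swing(config = cfg))
  )
  expect_equal(ts$average_exponent, base)
  expect_error(torque_sensitivity(swing_laws(), "swing", factors = c(1, -2)),
               "positive")
})
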