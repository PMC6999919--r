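test_that("characteristic movement times match their closed forms", {
  expect_equal(fall_time(0.162, 9.81), sqrt(2 * 0.162 / 9.81))
  expect_equal(fall_time(0.162, 9.81), 0.18174, tolerance = 1e-4)
  expect_equal(fall_time(4 * 0.162), 2 * fall_time(0.162))
  expect_equal(pendulum_period(9.81, 9.81), 2 * pi)
  expect_equal(pendulum_period(0.162, 9.81), 0.80743, tolerance = 1e-4)
  expect_error(fall_time(-1), "positive")
  expect_error(pendulum_period(0.1, 0), "positive")

  # under geometric similarity both scale as M^(1/6)
  m <- mass_grid()
  leg <- 0.16 * m^(1 / 3)
  expect_equal(fit_power_law(m, fall_time(leg))$exponent, 1 / 6,
               tolerance = 1e-10)
  expect_equal(fit_power_law(m, pendulum_period(leg))$exponent, 1 / 6,
               tolerance = 1e-10)
})

test_that("gravity-free swing delay matches a brute-force double integrator", {
  expect_equal(swing_delay_linear(2.52e-4, 0, 0.545), 0)
  expect_close(swing_delay_linear(2.52e-4, deg2rad(1), 0.5442), 5.685e-3,
               rel = 1e-3)
  # quarter delay for 4x torque (inverse square root)
  expect_equal(swing_delay_linear(1e-3, 0.5, 4 * 2) /
                 swing_delay_linear(1e-3, 0.5, 2), 0.5)
  expect_error(swing_delay_linear(1e-3, -0.1, 1), ">= 0")

  set.seed(42)
  for (i in 1:4) {
    moi <- 10^runif(1, -4, -1)
    mag <- runif(1, 0.1, 1.5)
    tq <- 10^runif(1, -1, 1)
    expect_close(swing_delay_linear(moi, mag, tq),
                 brute_swing_linear(moi, mag, tq, dt = 1e-6),
                 rel = 1e-3)
  }
})

test_that("gravity-free posture delay matches the bisected brute-force oracle", {
  expect_equal(posture_delay_linear(0.0262, 0, 3.41), 0)
  expect_close(posture_delay_linear(0.026244, 0.077807, 3.4133), 1.4445e-3,
               rel = 1e-3)
  expect_equal(posture_delay_linear(0.03, 2 * 0.1, 3) /
                 posture_delay_linear(0.03, 0.1, 3), 2)
  # homogeneous: scaling moi and torque together leaves the delay unchanged
  expect_equal(posture_delay_linear(7 * 0.03, 0.1, 7 * 3),
               posture_delay_linear(0.03, 0.1, 3))
  expect_equal(swing_delay_linear(5 * 1e-3, 0.4, 5 * 0.2),
               swing_delay_linear(1e-3, 0.4, 0.2))

  set.seed(43)
  for (i in 1:3) {
    moi <- 10^runif(1, -3, -1)
    om <- runif(1, 0.05, 0.5)
    tq <- 10^runif(1, -0.5, 0.5)
    expect_close(posture_delay_linear(moi, om, tq),
                 brute_posture_linear(moi, om, tq, dt = 1e-6),
                 rel = 1e-3)
  }
})

test_that("dimensionless velocity converts to angular velocity as v sqrt(g/L)/L", {
  expect_equal(dimensionless_velocity_to_angular(0, 0.3), 0)
  expect_close(dimensionless_velocity_to_angular(0.01, 0.162, 9.81),
               0.0778, rel = 1e-3)
  expect_error(dimensionless_velocity_to_angular(0.1, 0), "positive")
  # linear velocity v = v_nd sqrt(g L) scales as M^(1/6) under L ~ M^(1/3)
  m <- mass_grid()
  leg <- 0.16 * m^(1 / 3)
  v <- dimensionless_velocity_to_angular(0.2, leg) * leg
  expect_equal(fit_power_law(m, v)$exponent, 1 / 6, tolerance = 1e-10)
})

test_that("theoretical exponent table is exact", {
  tbl <- theoretical_exponents()
  expect_equal(nrow(tbl), 4)
  expect_equal(tbl$delay_exponent[tbl$task == "swing"], c(1 / 6, 1 / 3))
  expect_equal(tbl$delay_exponent[tbl$task == "posture"], c(1 / 6, 1 / 2))
  expect_equal(tbl$relative_exponent, c(0, 1 / 6, 0, 1 / 3))
  # delay and relative exponents always differ by the characteristic 1/6
  expect_equal(tbl$delay_exponent - tbl$relative_exponent, rep(1 / 6, 4))
  expect_equal(theoretical_exponent("posture", "cross_sectional_area")$delay_exponent,
               1 / 2)
  expect_error(theoretical_exponent("flight"), "arg")
})
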