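test_that("swing dynamics: equilibrium, torque, and gravity terms", {
  p <- swing_parameters(1)
  expect_equal(swing_ode(c(0, 0), p, 0), c(0, 0))
  expect_equal(swing_ode(c(0, 0), p, p$muscle_torque),
               c(0, p$muscle_torque / p$moment_of_inertia))
  k <- p$limb_mass * p$gravity * p$com_length / p$moment_of_inertia
  expect_equal(swing_ode(c(pi / 2, 0), p, 0)[2], -k)
  expect_equal(swing_ode(c(pi / 2, 0), p, 0, "destabilizing")[2], k)
  expect_equal(swing_ode(c(pi / 2, 0), p, 0, "off")[2], 0)
})

test_that("gravity-free nonlinear swing matches the closed form to 0.1%", {
  cfg0 <- analysis_config(swing_gravity = "off")
  set.seed(7)
  for (i in 1:5) {
    m <- 10^runif(1, -3, 4)
    mag <- runif(1, 1, 60)
    p <- swing_parameters(m)
    sim <- simulate_swing(p, mag, cfg0)
    expect_close(sim$inertial_delay,
                 swing_delay_linear(p$moment_of_inertia, deg2rad(mag),
                                    p$muscle_torque),
                 rel = 1e-3)
  }
})

test_that("bang-bang swing is terminally symmetric and comes to rest", {
  cfg <- analysis_config()
  for (case in list(c(1, 30), c(1e-3, 60), c(1e4, 60), c(10, 1))) {
    p <- swing_parameters(case[1])
    sim <- simulate_swing(p, case[2], cfg)
    final <- sim$trace[nrow(sim$trace), ]
    expect_lt(abs(final$angle - deg2rad(case[2]) / 2), 1e-6)
    expect_lt(abs(final$angular_velocity), 1e-6)
    # the applied torque is always at the bound, and the delay is the
    # final time stamp
    expect_true(all(abs(sim$trace$torque) == p$muscle_torque))
    expect_equal(sim$inertial_delay, max(sim$trace$time))
    expect_true(sim$converged)
  }
})

test_that("nonlinear swing with gravity matches the energy-quadrature oracle", {
  cfg <- analysis_config()
  for (case in list(c(1, 30), c(1e4, 60), c(0.1, 10))) {
    p <- swing_parameters(case[1])
    sim <- simulate_swing(p, case[2], cfg)
    expect_close(sim$inertial_delay, quad_swing_delay(p, case[2]),
                 rel = 1e-5)
  }
})

test_that("swing delay is invariant when MOI, M_limb L_COM, and torque scale together", {
  p <- swing_parameters(1)
  p2 <- p
  k <- 3.7
  p2$moment_of_inertia <- k * p$moment_of_inertia
  p2$limb_mass <- k * p$limb_mass # scales M_limb L_COM by k
  p2$muscle_torque <- k * p$muscle_torque
  expect_equal(simulate_swing(p2, 40)$inertial_delay,
               simulate_swing(p, 40)$inertial_delay, tolerance = 1e-8)
})

test_that("halving integrator tolerances moves the delay by < 0.01%", {
  p <- swing_parameters(10)
  d1 <- simulate_swing(p, 45, analysis_config())$inertial_delay
  d2 <- simulate_swing(p, 45, analysis_config(rtol = 5e-9,
                                              atol = 5e-11))$inertial_delay
  expect_lt(abs(d2 - d1) / d1, 1e-4)
})

test_that("swing delay surface is consistent and monotone in magnitude", {
  surf <- swing_surface_baseline()
  cfg <- baseline_config()
  expect_true(attr(surf, "complete"))
  expect_s3_class(surf, "inertial_delay_surface")
  expect_equal(nrow(surf), length(cfg$masses) * length(cfg$swing_magnitudes))

  # a single cell reproduces simulate_swing
  one <- surf[surf$mass_kg == 1e4 & surf$magnitude_deg == 60, ]
  expect_equal(one$delay_s,
               simulate_swing(swing_parameters(1e4), 60, cfg)$inertial_delay)

  # delays strictly increase with magnitude at every mass
  by_mass <- split(surf, surf$mass_kg)
  for (sub in by_mass) {
    expect_true(all(diff(sub$delay_s[order(sub$magnitude_deg)]) > 0))
  }
})
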