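test_that("inverted-pendulum dynamics: equilibrium, torque, unstable gravity", {
  p <- posture_parameters(1)
  moi <- p$body_mass * p$limb_length^2
  expect_equal(posture_ode(c(0, 0), p, 0), c(0, 0))
  expect_equal(posture_ode(c(0, 0), p, 2), c(0, 2 / moi))
  # small angles, no torque: destabilizing linearization (g/L) theta
  th <- 1e-4
  expect_equal(posture_ode(c(th, 0), p, 0)[2],
               (p$gravity / p$limb_length) * th, tolerance = 1e-8)
})

test_that("posture recovery satisfies its boundary conditions to 1e-6", {
  cfg <- analysis_config()
  for (case in list(c(1, 0.01), c(1, 0.49), c(1e-3, 0.2), c(1e4, 0.45))) {
    p <- posture_parameters(case[1])
    sol <- simulate_posture(p, case[2], cfg)
    expect_true(sol$feasible)
    expect_lt(abs(sol$residuals["angle"]), 1e-6)
    expect_lt(abs(sol$residuals["velocity"]), 1e-6)
    expect_true(sol$switch_time > 0 && sol$switch_time < sol$inertial_delay)
  }
})

test_that("gravity-free posture recovery matches the closed form and switch fraction", {
  # vanishing gravity: v_nd is rescaled so the initial angular velocity
  # stays finite while the gravity terms become negligible
  g_tiny <- 1e-8
  cfg <- analysis_config(gravity = g_tiny)
  p <- posture_parameters(1, config = cfg)
  moi <- p$body_mass * p$limb_length^2
  omega0 <- 0.0778
  v_nd <- omega0 / sqrt(g_tiny / p$limb_length)
  sol <- simulate_posture(p, v_nd, cfg)
  expect_true(sol$feasible)
  expect_close(sol$inertial_delay,
               posture_delay_linear(moi, omega0, p$muscle_torque),
               rel = 1e-3)
  # the double integrator switches at (2+sqrt(2))/2 * omega0/a, which is
  # sqrt(2)/2 of the total (1+sqrt(2)) * omega0/a
  expect_equal(sol$switch_time / sol$inertial_delay, sqrt(2) / 2,
               tolerance = 1e-3)
})

test_that("posture delay matches the energy-quadrature oracle with gravity", {
  cfg <- analysis_config()
  for (case in list(c(1, 0.2), c(1e4, 0.3))) {
    p <- posture_parameters(case[1])
    sol <- simulate_posture(p, case[2], cfg)
    expect_close(sol$inertial_delay, quad_posture_delay(p, case[2]),
                 rel = 1e-5)
  }
})

test_that("delay vanishes continuously as the perturbation goes to zero", {
  p <- posture_parameters(1)
  expect_equal(simulate_posture(p, 0)$inertial_delay, 0)
  expect_lt(simulate_posture(p, 1e-4)$inertial_delay, 1e-4)
})

test_that("capture limit: 10-tonne value, energy-bound oracle, monotonicity", {
  cfg <- analysis_config()
  p <- posture_parameters(1e4)
  lim <- max_rejectable_perturbation(p, cfg)
  expect_equal(lim, analytic_capture_limit(p), tolerance = 5e-3)
  # beyond the limit the recovery is infeasible; just below it is feasible
  expect_false(simulate_posture(p, lim + 0.01, cfg)$feasible)
  expect_true(simulate_posture(p, lim - 0.01, cfg)$feasible)
  # stronger muscles never shrink the recoverable set
  p_strong <- p
  p_strong$muscle_torque <- 1.5 * p$muscle_torque
  expect_gt(max_rejectable_perturbation(p_strong, cfg), lim)
  # torque above the maximal gravity torque: no finite limit
  expect_message(
    out <- max_rejectable_perturbation(posture_parameters(1), cfg),
    "no finite"
  )
  expect_identical(out, Inf)
})

test_that("posture delay surface is consistent, monotone, and flags infeasible cells", {
  surf <- posture_surface_baseline()
  cfg <- baseline_config()
  expect_true(attr(surf, "complete"))
  one <- surf[surf$mass_kg == 1e4 & abs(surf$vnd - 0.49) < 1e-9, ]
  expect_equal(one$delay_s,
               simulate_posture(posture_parameters(1e4), 0.49,
                                cfg)$inertial_delay)
  for (sub in split(surf, surf$mass_kg)) {
    d <- sub$delay_s[order(sub$vnd)]
    expect_true(all(diff(d) > 0))
    # super-linear growth near the capture limit: the last log-log slope
    # exceeds the first for the largest animal
    if (sub$mass_kg[1] == 1e4) {
      slopes <- diff(log(d)) / diff(log(sort(sub$vnd)))
      expect_gt(slopes[length(slopes)], slopes[1])
    }
  }
  # perturbations beyond the 10 t capture limit are flagged, not errored
  small <- delay_surface_posture(masses = c(1, 1e4), vnd_grid = c(0.1, 0.6),
                                 config = cfg)
  expect_false(attr(small, "complete"))
  expect_false(small$converged[small$mass_kg == 1e4 & small$vnd == 0.6])
  expect_true(small$converged[small$mass_kg == 1 & small$vnd == 0.6])
})

test_that("shooting solution is robust to integrator tolerance changes", {
  p <- posture_parameters(100)
  s1 <- simulate_posture(p, 0.3, analysis_config())
  s2 <- simulate_posture(p, 0.3, analysis_config(rtol = 5e-9, atol = 5e-11))
  expect_equal(s1$switch_time, s2$switch_time, tolerance = 1e-6)
  expect_equal(s1$inertial_delay, s2$inertial_delay, tolerance = 1e-6)
})
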