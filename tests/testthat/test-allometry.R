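test_that("scaling laws evaluate as a * M^b and reject bad input", {
  laws <- swing_laws()
  limb_mass <- as_scaling_law(laws, "forelimb_mass")
  expect_equal(evaluate_scaling_law(limb_mass, 1), 5.82e-2)
  arm <- as_scaling_law(laws, "triceps_moment_arm")
  expect_equal(evaluate_scaling_law(arm, 100), 8.70e-3 * 100^0.41,
               tolerance = 1e-12)
  expect_equal(evaluate_scaling_law(arm, 100), 5.748e-2, tolerance = 1e-3)
  for (q in laws$quantity) {
    law <- as_scaling_law(laws, q)
    expect_equal(evaluate_scaling_law(law, 1), law$coefficient)
  }
  expect_error(evaluate_scaling_law(limb_mass, 0), "positive")
  expect_error(evaluate_scaling_law(limb_mass, -3), "positive")
  expect_error(scaling_law(-1, 0.5), "positive")
  expect_error(scaling_law(2, 0.5, coefficient_ci = c(3, 4)), "interval")
})

test_that("scaling laws are multiplicative: value(kM)/value(M) = k^b", {
  set.seed(11)
  for (i in 1:20) {
    law <- scaling_law(runif(1, 1e-4, 10), runif(1, -1, 2))
    m <- 10^runif(1, -3, 4)
    k <- 10^runif(1, -2, 2)
    expect_equal(evaluate_scaling_law(law, k * m) / evaluate_scaling_law(law, m),
                 k^law$exponent, tolerance = 1e-10)
  }
})

test_that("the muscle-torque chain reproduces the published 1-kg values", {
  tri <- triceps_group()
  ank <- ankle_extensor_group()
  # stress * (m / rho) / l, frozen from direct arithmetic on the tables
  expect_equal(muscle_force(tri, 1), 2e5 * (6.20e-3 / 1060) / 1.87e-2,
               tolerance = 1e-12)
  expect_equal(muscle_force(tri, 1), 62.56, tolerance = 1e-3)
  expect_equal(muscle_force(ank, 1), 90.78, tolerance = 1e-3)
  expect_equal(muscle_torque(tri, 1), 0.5442, tolerance = 1e-3)
  expect_equal(muscle_torque(ank, 1), 3.4133, tolerance = 1e-3)

  # linear in stress; leg multiplier is an exact factor
  cfg2 <- analysis_config(isometric_stress = 40e4)
  expect_equal(muscle_force(triceps_group(config = cfg2), 5),
               2 * muscle_force(tri, 5))
  ank1 <- ank
  ank1$leg_multiplier <- 1L
  expect_equal(muscle_torque(ank, 7), 4 * muscle_torque(ank1, 7))
})

test_that("muscle torque scales as M under geometric + dynamic similarity", {
  # mass ~ M, lengths and arm ~ M^(1/3): F ~ M^(2/3), T = F R ~ M
  grp <- muscle_group(scaling_law(6e-3, 1), scaling_law(2e-2, 1 / 3),
                      scaling_law(9e-3, 1 / 3))
  m <- mass_grid()
  fit <- fit_power_law(m, vapply(m, function(x) muscle_torque(grp, x),
                                 numeric(1)))
  expect_equal(fit$exponent, 1, tolerance = 1e-10)
})

test_that("task parameter constructors evaluate the tables at the body mass", {
  sp <- swing_parameters(1)
  expect_equal(sp$moment_of_inertia, 2.52e-4)
  expect_equal(sp$limb_mass, 5.82e-2)
  expect_equal(sp$com_length, 5.64e-2)
  expect_equal(sp$gravity, 9.81)

  pp <- posture_parameters(1)
  expect_equal(pp$limb_length, (1.61e-1 + 1.63e-1) / 2)
  expect_equal(pp$body_mass, 1)
  expect_equal(pp$muscle_torque, muscle_torque(ankle_extensor_group(), 1))

  expect_error(swing_parameters(-1), "positive")
  expect_error(posture_parameters(c(1, 2)), "single")

  # deterministic pure functions of (mass, config)
  expect_identical(swing_parameters(37.5), swing_parameters(37.5))
})

test_that("mass grid is geometric, inclusive, and spans 1 g to 10 t", {
  m <- mass_grid()
  expect_length(m, 7)
  expect_equal(m[1], 1e-3)
  expect_equal(m[7], 1e4)
  expect_equal(diff(log10(m)), rep(7 / 6, 6))
  expect_equal(mass_grid(2, 1, 100), c(1, 100))
  expect_error(mass_grid(1), "at least 2")
  expect_error(mass_grid(5, 10, 1), "m_min < m_max")
})

test_that("scaling tables round-trip through CSV", {
  tbl <- posture_laws()
  path <- withr::local_tempfile(fileext = ".csv")
  write_scaling_table(tbl, path)
  back <- read_scaling_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
  expect_error(as_scaling_law(tbl, "no_such_law"), "exactly one law")
  expect_error(validate_scaling_table(tbl[, 1:3]), "missing columns")
})
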