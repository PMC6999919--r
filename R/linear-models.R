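#' Characteristic movement times
#'
#' Closed-form time scales against which response times are judged:
#' `fall_time()` is the time to free-fall through one leg length,
#' `sqrt(2 L / g)`; `pendulum_period()` is the natural period of a simple
#' pendulum of that length, `2 pi sqrt(L / g)`. Under geometric similarity
#' (`L` proportional to `M^(1/3)`) both scale as `M^(1/6)`.
#'
#' @param leg_length Leg length, m (positive).
#' @param g Gravitational acceleration, m/s^2 (positive).
#' @return Time in seconds.
#' @examples
#' fall_time(0.162, 9.81)       # ~0.182 s for a 1 kg animal
#' pendulum_period(0.162, 9.81) # ~0.808 s
#' @export
fall_time <- function(leg_length, g = 9.81) {
  check_positive(leg_length, "leg_length")
  check_positive(g, "g")
  sqrt(2 * leg_length / g)
}

#' @rdname fall_time
#' @export
pendulum_period <- function(leg_length, g = 9.81) {
  check_positive(leg_length, "leg_length")
  check_positive(g, "g")
  2 * pi * sqrt(leg_length / g)
}

#' Linearized (gravity-free) inertial delays
#'
#' Closed-form minimum movement times for the two tasks when gravity is
#' ignored and the dynamics reduce to a torque-limited double integrator.
#'
#' `swing_delay_linear()` is the rest-to-rest bang-bang time to move a rotor
#' of inertia `moi` through a total angle `magnitude` under torque bound
#' `torque`: `t = 2 sqrt(moi * magnitude / torque)`.
#'
#' `posture_delay_linear()` is the minimum time for a single-switch bang-bang
#' torque to return the rotor to rest at the origin from an initial angular
#' velocity `omega0` at the origin: `t = (1 + sqrt(2)) * moi * omega0 /
#' torque` (linear in the perturbation).
#'
#' Both serve as the analytic oracle for the nonlinear simulators in the
#' gravity-free limit.
#'
#' @param moi Moment of inertia, kg m^2 (positive).
#' @param magnitude Total angular excursion of the move, rad (>= 0).
#' @param omega0 Magnitude of the initial angular velocity, rad/s (>= 0).
#' @param torque Torque bound, N m (positive).
#' @return Time in seconds.
#' @examples
#' swing_delay_linear(2.52e-4, 1 * pi / 180, 0.545)   # ~5.7 ms
#' posture_delay_linear(0.0262, 0.0779, 3.41)         # ~1.45 ms
#' @export
swing_delay_linear <- function(moi, magnitude, torque) {
  check_positive(moi, "moi")
  check_positive(torque, "torque")
  if (any(magnitude < 0)) stop("magnitude must be >= 0 rad", call. = FALSE)
  2 * sqrt(moi * magnitude / torque)
}

#' @rdname swing_delay_linear
#' @export
posture_delay_linear <- function(moi, omega0, torque) {
  check_positive(moi, "moi")
  check_positive(torque, "torque")
  if (any(omega0 < 0)) stop("omega0 must be >= 0 rad/s", call. = FALSE)
  (1 + sqrt(2)) * moi * omega0 / torque
}

#' Angular velocity from a dimensionless velocity perturbation
#'
#' Perturbations are scaled across animal sizes by a Froude-like
#' dimensionless velocity `v_nd = v / sqrt(g L)`. The corresponding initial
#' angular velocity of a pendulum of length `L` is
#' `omega0 = v / L = v_nd * sqrt(g / L)`.
#'
#' @param v_nd Dimensionless velocity (>= 0).
#' @param limb_length Pendulum length, m (positive).
#' @param g Gravitational acceleration, m/s^2.
#' @return Angular velocity, rad/s.
#' @examples
#' dimensionless_velocity_to_angular(0.01, 0.162) # ~0.078 rad/s
#' @export
dimensionless_velocity_to_angular <- function(v_nd, limb_length, g = 9.81) {
  check_positive(limb_length, "limb_length")
  if (any(v_nd < 0)) stop("v_nd must be >= 0", call. = FALSE)
  v_nd * sqrt(g / limb_length)
}

#' Theoretical scaling exponents for inertial delay
#'
#' Under geometric similarity of the skeleton (lengths ~ M^(1/3), segment
#' masses ~ M, moments of inertia ~ M^(5/3)) the linearized models predict the
#' body-mass exponent of inertial delay in closed form, for two muscle-force
#' scaling regimes: dynamic similarity (force ~ M) or cross-sectional area
#' (force ~ M^(2/3)). The relative exponent subtracts the characteristic-time
#' exponent 1/6.
#'
#' @param task `"swing"` or `"posture"`.
#' @param force_scaling `"dynamic_similarity"` or `"cross_sectional_area"`.
#' @return `theoretical_exponent()` returns a one-row tibble with columns
#'   `task, force_scaling, delay_exponent, relative_exponent`;
#'   `theoretical_exponents()` returns all four rows.
#' @examples
#' theoretical_exponents()
#' @export
theoretical_exponent <- function(task = c("swing", "posture"),
                                 force_scaling = c("dynamic_similarity",
                                                   "cross_sectional_area")) {
  task <- match.arg(task)
  force_scaling <- match.arg(force_scaling)
  delay <- switch(
    paste(task, force_scaling),
    "swing dynamic_similarity"    = 1 / 6,
    "swing cross_sectional_area"  = 1 / 3,
    "posture dynamic_similarity"  = 1 / 6,
    "posture cross_sectional_area" = 1 / 2
  )
  tibble::tibble(task = task, force_scaling = force_scaling,
                 delay_exponent = delay,
                 relative_exponent = delay - 1 / 6)
}

#' @rdname theoretical_exponent
#' @export
theoretical_exponents <- function() {
  grid <- expand.grid(
    force_scaling = c("dynamic_similarity", "cross_sectional_area"),
    task = c("swing", "posture"), stringsAsFactors = FALSE
  )
  purrr::map2_dfr(grid$task, grid$force_scaling, theoretical_exponent)
}

check_positive <- function(x, label) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(label, " must be positive and finite", call. = FALSE)
  }
  invisible(x)
}
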