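# Independent oracles used across the suite. These deliberately avoid the
# package's integrator and solvers: fixed-step time stepping for the
# linearized models, energy-conservation quadrature for the nonlinear
# pendula, and a closed-form energy bound for the capture limit.

# Bang-bang rest-to-rest double integrator, stepped at dt: accelerate at
# +a until the angle crosses zero (start at -magnitude/2), then -a until
# the velocity crosses zero. Returns the elapsed time.
brute_swing_linear <- function(moi, magnitude, torque, dt = 1e-6) {
  a <- torque / moi
  th <- -magnitude / 2
  v <- 0
  t <- 0
  while (th < 0) {
    v <- v + a * dt
    th <- th + v * dt
    t <- t + dt
  }
  while (v > 0) {
    v <- v - a * dt
    th <- th + v * dt
    t <- t + dt
  }
  t
}

# Double integrator from (0, -omega0): +a until the switch time, then -a
# until the velocity returns to zero; the switch time is bisected so the
# final angle is zero. Returns the total time.
brute_posture_linear <- function(moi, omega0, torque, dt = 1e-6) {
  a <- torque / moi
  run <- function(ts) {
    th <- 0
    v <- -omega0
    t <- 0
    while (t < ts) {
      v <- v + a * dt
      th <- th + v * dt
      t <- t + dt
    }
    while (v > 0) {
      v <- v - a * dt
      th <- th + v * dt
      t <- t + dt
    }
    c(theta = th, time = t)
  }
  # reversal happens at omega0 / a; switching before that cannot return
  lo <- omega0 / a
  hi <- 4 * omega0 / a
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (run(mid)["theta"] < 0) lo <- mid else hi <- mid
  }
  unname(run((lo + hi) / 2)["time"])
}

# Energy-conservation quadrature for the nonlinear hanging pendulum under
# constant torque: time for the first arc from rest at theta0 = -dtheta/2
# to the hanging equilibrium; the full bang-bang move is twice this by
# symmetry. v^2(theta) = 2 [a_T (theta - theta0) + k (cos theta - cos theta0)]
# with a_T = T/MOI and k = M_limb g L_COM / MOI (restoring).
quad_swing_delay <- function(params, magnitude_deg) {
  dtheta <- magnitude_deg * pi / 180
  th0 <- -dtheta / 2
  a_t <- params$muscle_torque / params$moment_of_inertia
  k <- params$limb_mass * params$gravity * params$com_length /
    params$moment_of_inertia
  v <- function(th) sqrt(2 * (a_t * (th - th0) + k * (cos(th) - cos(th0))))
  2 * stats::integrate(function(th) 1 / v(th), th0, 0,
                       rel.tol = 1e-10, subdivisions = 2000L)$value
}

# Same idea for the inverted pendulum: forward arc (counter-torque +T)
# v1^2 = omega0^2 + 2 a_T theta + 2 a_g (1 - cos theta); reversed-torque
# arc ending at upright rest v2^2 = -2 a_T theta + 2 a_g (1 - cos theta).
# The optimal switch angle solves v1^2 = v2^2 on the return; the delay is
# the sum of the three quadrature times (fall, return to switch, brake).
quad_posture_delay <- function(params, v_nd) {
  a_t <- params$muscle_torque / (params$body_mass * params$limb_length^2)
  a_g <- params$gravity / params$limb_length
  omega0 <- v_nd * sqrt(params$gravity / params$limb_length)
  v1sq <- function(th) omega0^2 + 2 * a_t * th + 2 * a_g * (1 - cos(th))
  # braking arc to upright rest: both the reversed torque and (below
  # upright) gravity decelerate, so v2^2 grows with distance from vertical
  v2sq <- function(th) -2 * a_t * th + 2 * a_g * (1 - cos(th))
  # the reversal root lies between the critical angle (where v1sq is
  # minimal) and zero; beyond the critical angle gravity re-accelerates
  th_star <- asin(min(1, a_t / a_g))
  th_m <- stats::uniroot(v1sq, c(-th_star, -1e-12), tol = 1e-14)$root
  # v1sq = v2sq: the gravity terms cancel, leaving the exact switch angle
  th_s <- -omega0^2 / (4 * a_t)
  stopifnot(th_s > th_m)
  # each arc time has a 1/sqrt singularity where v = 0 (at th_m for v1, at
  # 0 for v2); substitute theta = singularity +/- u^2 to regularize
  t_from_thm <- function(upper) { # int_{th_m}^{upper} dth / sqrt(v1sq)
    stats::integrate(function(u) 2 * u / sqrt(v1sq(th_m + u^2)),
                     0, sqrt(upper - th_m),
                     rel.tol = 1e-11, subdivisions = 2000L)$value
  }
  t_brake <- stats::integrate(function(u) 2 * u / sqrt(v2sq(-u^2)),
                              0, sqrt(-th_s),
                              rel.tol = 1e-11, subdivisions = 2000L)$value
  t_from_thm(0) + t_from_thm(th_s) + t_brake
}

# Closed-form capture limit from the energy argument: the fall can be
# arrested iff the kinetic energy is absorbed before the critical angle
# asin(T / (M g L)) where gravity overwhelms the counter-torque.
analytic_capture_limit <- function(params) {
  a_t <- params$muscle_torque / (params$body_mass * params$limb_length^2)
  a_g <- params$gravity / params$limb_length
  if (a_t >= a_g) return(Inf)
  th_star <- asin(a_t / a_g)
  omega_max <- sqrt(2 * (a_t * th_star - a_g * (1 - cos(th_star))))
  omega_max / sqrt(params$gravity / params$limb_length)
}
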