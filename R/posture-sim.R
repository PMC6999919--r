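#' Posture-task inverted-pendulum dynamics
#'
#' Angular acceleration of the point-mass inverted pendulum representing the
#' whole body during posture recovery. The angle is measured from upright
#' vertical, and gravity is destabilizing:
#' `theta'' = torque / (M * L^2) + (g / L) * sin(theta)`.
#'
#' @param state Numeric length-2: angle (rad) and angular velocity (rad/s).
#' @param params A [posture_parameters()] row.
#' @param torque Applied torque, N m (signed).
#' @return Numeric length-2 state derivative.
#' @export
posture_ode <- function(state, params, torque) {
  moi <- params$body_mass * params$limb_length^2
  c(state[2],
    torque / moi + (params$gravity / params$limb_length) * sin(state[1]))
}

# Largest |angle| from which the counter-torque can still arrest the fall:
# net torque is zero at asin(T / (M g L)); beyond it gravity wins. Inf when
# the torque exceeds the maximal gravitational torque (or gravity is off).
posture_critical_angle <- function(params) {
  mgl <- params$body_mass * params$gravity * params$limb_length
  if (params$gravity <= 0 || params$muscle_torque >= mgl) Inf
  else asin(params$muscle_torque / mgl)
}

# Integrate the first arc (counter-torque +T) from (0, -omega0) until the
# velocity reverses; detects escape past the critical angle. Returns the
# reversal state or feasible = FALSE.
posture_arc1 <- function(params, omega0, config, t_cap) {
  tq <- params$muscle_torque
  deriv <- function(t, y) posture_ode(y, params, tq)
  th_crit <- posture_critical_angle(params)
  events <- list(list(fun = function(t, y) y[2], direction = 1))
  if (is.finite(th_crit)) {
    events <- c(events,
                list(list(fun = function(t, y) y[1] + th_crit, direction = -1)))
  }
  sol <- rk45_integrate(deriv, y0 = c(0, -omega0), t0 = 0, t_max = t_cap,
                        rtol = config$rtol, atol = config$atol,
                        events = events)
  feasible <- sol$status == "event" && sol$event$index == 1L
  list(sol = sol, feasible = feasible)
}

#' Simulate one posture-recovery movement
#'
#' Minimum-time rejection of a forward velocity perturbation by a
#' torque-limited inverted pendulum. The pendulum starts upright with a
#' clockwise angular velocity `-v_nd * sqrt(g / L)`; the counter-torque
#' `+T_musc` is applied until an optimized switch time, then `-T_musc`, such
#' that the pendulum reaches the upright position exactly as its velocity
#' reaches zero. The switch time is found by shooting: the position residual
#' at the instant the velocity crosses zero is driven to zero with a
#' safeguarded scalar root-finder bracketed between the velocity-reversal
#' time and the time the angle first returns to zero under the counter-torque.
#'
#' @param params A [posture_parameters()] row.
#' @param v_nd Perturbation magnitude, dimensionless velocity (>= 0).
#' @param config An [analysis_config()].
#' @return An object of class `posture_simulation`: a list with `trace`
#'   (tibble of `time`, `angle`, `angular_velocity`, `torque`),
#'   `inertial_delay` (s), `switch_time` (s), `feasible`, `residuals`
#'   (terminal angle and velocity), `v_nd`, and `params`. When the
#'   perturbation exceeds the capture limit the result has `feasible = FALSE`
#'   and `inertial_delay = NA`.
#' @examples
#' sol <- simulate_posture(posture_parameters(1), 0.01)
#' sol$inertial_delay # ~1.5 ms
#' @export
simulate_posture <- function(params, v_nd, config = analysis_config()) {
  stopifnot(inherits(params, "posture_parameters"))
  if (!is.numeric(v_nd) || length(v_nd) != 1L || v_nd < 0) {
    stop("v_nd must be a single number >= 0", call. = FALSE)
  }
  tq <- params$muscle_torque
  moi <- params$body_mass * params$limb_length^2
  omega0 <- dimensionless_velocity_to_angular(v_nd, params$limb_length,
                                              params$gravity)

  if (omega0 == 0) {
    return(structure(
      list(trace = tibble::tibble(time = 0, angle = 0, angular_velocity = 0,
                                  torque = 0),
           inertial_delay = 0, switch_time = 0, feasible = TRUE,
           residuals = c(angle = 0, velocity = 0), v_nd = v_nd,
           params = params),
      class = "posture_simulation"
    ))
  }

  t_lin <- posture_delay_linear(moi, omega0, tq)
  t_cap <- 100 * t_lin

  a1 <- posture_arc1(params, omega0, config, t_cap)
  if (!a1$feasible) {
    return(structure(
      list(trace = NULL, inertial_delay = NA_real_, switch_time = NA_real_,
           feasible = FALSE, residuals = NULL, v_nd = v_nd, params = params),
      class = "posture_simulation"
    ))
  }
  t_rev <- a1$sol$event$time
  y_rev <- a1$sol$event$state # velocity ~ 0 at the lowest angle

  deriv_fwd <- function(t, y) posture_ode(y, params, tq)
  deriv_rev <- function(t, y) posture_ode(y, params, -tq)

  # continue the counter-torque arc until the angle returns to zero: upper
  # bracket for the switch time (switching there mirrors the fall and stops
  # at a positive angle).
  cont <- rk45_integrate(
    deriv_fwd, y0 = y_rev, t0 = t_rev, t_max = t_cap,
    rtol = config$rtol, atol = config$atol,
    events = list(list(fun = function(t, y) y[1], direction = 1))
  )
  if (cont$status != "event") {
    stop(sprintf(
      "posture recovery arc did not return to vertical within %.3g s (M = %.3g kg, v_nd = %.3g)",
      t_cap, params$body_mass, v_nd), call. = FALSE)
  }
  t_up <- cont$event$time

  # state on the counter-torque arc at a candidate switch time
  arc1_state <- function(ts) {
    sol <- rk45_integrate(deriv_fwd, y0 = y_rev, t0 = t_rev, t_max = ts,
                          rtol = config$rtol, atol = config$atol)
    list(t = sol$times[length(sol$times)],
         y = sol$states[nrow(sol$states), ])
  }

  # terminal angle when switching at ts; +1 sentinel if the reversed torque
  # never brings the velocity to zero (overshoot past the critical angle)
  arc2_from <- function(ts, y_sw) {
    rk45_integrate(deriv_rev, y0 = y_sw, t0 = ts, t_max = ts + t_cap,
                   rtol = config$rtol, atol = config$atol,
                   events = list(list(fun = function(t, y) y[2],
                                      direction = -1)))
  }
  residual <- function(ts) {
    st <- arc1_state(ts)
    sol2 <- arc2_from(st$t, st$y)
    if (sol2$status != "event") return(1)
    sol2$event$state[1]
  }

  lo <- t_rev + (t_up - t_rev) * 1e-9
  root <- stats::uniroot(residual, lower = lo, upper = t_up,
                         tol = max(1e-14, t_up * 1e-12))
  t_switch <- root$root

  st <- arc1_state(t_switch)
  sol2 <- arc2_from(st$t, st$y)
  t_f <- sol2$event$time
  res <- c(angle = sol2$event$state[1], velocity = sol2$event$state[2])

  n1 <- length(a1$sol$times)
  pre <- rk45_integrate(deriv_fwd, y0 = c(0, -omega0), t0 = 0,
                        t_max = t_switch,
                        rtol = config$rtol, atol = config$atol)
  trace <- tibble::tibble(
    time = c(pre$times, sol2$times[-1]),
    angle = c(pre$states[, 1], sol2$states[-1, 1]),
    angular_velocity = c(pre$states[, 2], sol2$states[-1, 2]),
    torque = c(rep(tq, length(pre$times)),
               rep(-tq, length(sol2$times) - 1L))
  )
  structure(
    list(trace = trace, inertial_delay = t_f, switch_time = t_switch,
         feasible = TRUE, residuals = res, v_nd = v_nd, params = params),
    class = "posture_simulation"
  )
}

#' @export
print.posture_simulation <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf(
      "<posture_simulation> M = %.3g kg, v_nd = %.3g: inertial delay %.4g ms (switch at %.4g ms)\n",
      x$params$body_mass, x$v_nd, 1e3 * x$inertial_delay,
      1e3 * x$switch_time))
  } else {
    cat(sprintf(
      "<posture_simulation> M = %.3g kg, v_nd = %.3g: infeasible (beyond the capture limit)\n",
      x$params$body_mass, x$v_nd))
  }
  invisible(x)
}

#' Capture limit of the posture task
#'
#' Largest dimensionless-velocity perturbation from which the inverted
#' pendulum can still return to upright rest, found by bisection on the
#' feasibility of the recovery (to 1e-3 absolute in `v_nd`). When the muscle
#' torque exceeds the maximal gravitational torque (`T >= M g L`, always the
#' case with gravity off) every perturbation is recoverable and `Inf` is
#' returned with a message.
#'
#' @param params A [posture_parameters()] row.
#' @param config An [analysis_config()].
#' @param tol Absolute bisection tolerance on `v_nd`.
#' @return The capture limit (dimensionless velocity), or `Inf`.
#' @examples
#' \donttest{
#' max_rejectable_perturbation(posture_parameters(1e4)) # ~0.49
#' }
#' @export
max_rejectable_perturbation <- function(params, config = analysis_config(),
                                        tol = 1e-3) {
  stopifnot(inherits(params, "posture_parameters"))
  if (!is.finite(posture_critical_angle(params))) {
    message("muscle torque exceeds the maximal gravity torque: ",
            "no finite capture limit")
    return(Inf)
  }
  feasible <- function(v_nd) {
    omega0 <- dimensionless_velocity_to_angular(v_nd, params$limb_length,
                                                params$gravity)
    moi <- params$body_mass * params$limb_length^2
    t_cap <- 100 * posture_delay_linear(moi, omega0, params$muscle_torque)
    posture_arc1(params, omega0, config, t_cap)$feasible
  }
  lo <- 0
  hi <- 0.1
  while (feasible(hi)) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e3) stop("capture-limit search did not bracket", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Inertial-delay surface for the posture task
#'
#' Runs [simulate_posture()] over a body-mass grid crossed with a grid of
#' dimensionless-velocity perturbations.
#'
#' @param laws Scaling-law tibble in the [posture_laws()] schema.
#' @param masses Body masses, kg.
#' @param vnd_grid Perturbation magnitudes, dimensionless velocity.
#' @param config An [analysis_config()].
#' @return A tibble of class `inertial_delay_surface` with columns `mass_kg`,
#'   `vnd`, `delay_s`, `converged`, and attributes `task = "posture"` and
#'   `complete`. Infeasible or failed cells are flagged `converged = FALSE`.
#' @export
delay_surface_posture <- function(laws = posture_laws(),
                                  masses = NULL,
                                  vnd_grid = NULL,
                                  config = analysis_config()) {
  masses <- masses %||% config$masses
  vnd_grid <- vnd_grid %||% config$vnd_grid
  stopifnot(length(masses) >= 1, length(vnd_grid) >= 1)
  grid <- tidyr::expand_grid(mass_kg = masses, vnd = vnd_grid)
  cells <- purrr::pmap(grid, function(mass_kg, vnd) {
    pars <- posture_parameters(mass_kg, laws, config)
    tryCatch({
      sol <- simulate_posture(pars, vnd, config)
      list(delay = sol$inertial_delay, ok = isTRUE(sol$feasible))
    }, error = function(e) {
      warning("posture cell failed (M = ", signif(mass_kg, 3), " kg, v_nd = ",
              signif(vnd, 3), "): ", conditionMessage(e), call. = FALSE)
      list(delay = NA_real_, ok = FALSE)
    })
  })
  out <- dplyr::mutate(grid,
                       delay_s = purrr::map_dbl(cells, "delay"),
                       converged = purrr::map_lgl(cells, "ok"))
  structure(out,
            class = c("inertial_delay_surface", class(out)),
            task = "posture",
            complete = all(out$converged))
}
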