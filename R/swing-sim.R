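#' Swing-task pendulum dynamics
#'
#' Angular acceleration of the distributed-mass swing-limb pendulum under an
#' applied torque. The angle is measured from the hanging (downward)
#' equilibrium; with the default `"restoring"` gravity orientation the
#' equation of motion is
#' `theta'' = torque / MOI - (M_limb * g * L_COM / MOI) * sin(theta)`.
#'
#' @param state Numeric length-2: angle (rad) and angular velocity (rad/s).
#' @param params A [swing_parameters()] row.
#' @param torque Applied torque, N m (signed).
#' @param gravity_mode `"restoring"`, `"destabilizing"`, or `"off"`.
#' @return Numeric length-2: the state derivative (rad/s, rad/s^2).
#' @export
swing_ode <- function(state, params, torque,
                      gravity_mode = c("restoring", "destabilizing", "off")) {
  gravity_mode <- match.arg(gravity_mode)
  gsign <- switch(gravity_mode, restoring = -1, destabilizing = 1, off = 0)
  k <- gsign * params$limb_mass * params$gravity * params$com_length /
    params$moment_of_inertia
  c(state[2], torque / params$moment_of_inertia + k * sin(state[1]))
}

#' Simulate one bang-bang swing movement
#'
#' Minimum-time repositioning of the swing limb: the pendulum starts at rest
#' at an angle of `-magnitude/2` (half the total excursion, clockwise),
#' maximal torque `+T_musc` is applied until the angle crosses zero, the
#' torque switches to `-T_musc`, and the simulation stops when the angular
#' velocity crosses zero — by symmetry at `+magnitude/2`. The elapsed time is
#' the inertial delay.
#'
#' @param params A [swing_parameters()] row.
#' @param magnitude Total angular excursion of the movement, degrees (> 0).
#' @param config An [analysis_config()]; supplies integrator tolerances and
#'   the gravity orientation.
#' @return An object of class `swing_simulation`: a list with `trace` (tibble
#'   of `time`, `angle`, `angular_velocity`, `torque`), `inertial_delay` (s),
#'   `switch_time` (s), `converged`, `magnitude`, and `params`.
#' @examples
#' sim <- simulate_swing(swing_parameters(1), 30)
#' sim$inertial_delay # ~0.031 s
#' @export
simulate_swing <- function(params, magnitude, config = analysis_config()) {
  stopifnot(inherits(params, "swing_parameters"))
  if (!is.numeric(magnitude) || length(magnitude) != 1L || magnitude <= 0) {
    stop("magnitude must be a single positive number of degrees", call. = FALSE)
  }
  dtheta <- magnitude * pi / 180
  tq <- params$muscle_torque
  deriv_fwd <- function(t, y) swing_ode(y, params, tq, config$swing_gravity)
  deriv_rev <- function(t, y) swing_ode(y, params, -tq, config$swing_gravity)

  t_lin <- swing_delay_linear(params$moment_of_inertia, dtheta, tq)
  t_cap <- 100 * t_lin

  arc1 <- rk45_integrate(
    deriv_fwd, y0 = c(-dtheta / 2, 0), t0 = 0, t_max = t_cap,
    rtol = config$rtol, atol = config$atol,
    events = list(list(fun = function(t, y) y[1], direction = 1))
  )
  if (arc1$status != "event") {
    stop(sprintf(
      "swing arc 1 did not reach zero angle within %.3g s (status: %s; M = %.3g kg, magnitude = %.3g deg)",
      t_cap, arc1$status, params$body_mass, magnitude), call. = FALSE)
  }
  t_sw <- arc1$event$time

  arc2 <- rk45_integrate(
    deriv_rev, y0 = arc1$event$state, t0 = t_sw, t_max = t_cap,
    rtol = config$rtol, atol = config$atol,
    events = list(list(fun = function(t, y) y[2], direction = -1))
  )
  if (arc2$status != "event") {
    stop(sprintf(
      "swing arc 2 did not come to rest within %.3g s (status: %s; M = %.3g kg, magnitude = %.3g deg)",
      t_cap, arc2$status, params$body_mass, magnitude), call. = FALSE)
  }

  n1 <- length(arc1$times)
  trace <- tibble::tibble(
    time = c(arc1$times, arc2$times[-1]),
    angle = c(arc1$states[, 1], arc2$states[-1, 1]),
    angular_velocity = c(arc1$states[, 2], arc2$states[-1, 2]),
    torque = c(rep(tq, n1), rep(-tq, length(arc2$times) - 1L))
  )
  structure(
    list(trace = trace,
         inertial_delay = arc2$event$time,
         switch_time = t_sw,
         converged = TRUE,
         magnitude = magnitude,
         params = params),
    class = "swing_simulation"
  )
}

#' @export
print.swing_simulation <- function(x, ...) {
  cat(sprintf(
    "<swing_simulation> M = %.3g kg, %.3g deg: inertial delay %.4g ms (switch at %.4g ms)\n",
    x$params$body_mass, x$magnitude, 1e3 * x$inertial_delay,
    1e3 * x$switch_time))
  invisible(x)
}

#' Inertial-delay surface for the swing task
#'
#' Runs [simulate_swing()] over a body-mass grid crossed with a grid of
#' movement magnitudes.
#'
#' @param laws Scaling-law tibble in the [swing_laws()] schema.
#' @param masses Body masses, kg.
#' @param magnitudes Total movement magnitudes, degrees.
#' @param config An [analysis_config()].
#' @return A tibble of class `inertial_delay_surface` with columns `mass_kg`,
#'   `magnitude_deg`, `delay_s`, `converged`, and attributes `task = "swing"`
#'   and `complete`. Cells whose simulation fails are flagged
#'   `converged = FALSE` with `delay_s = NA`.
#' @examples
#' \donttest{
#' delay_surface_swing(swing_laws(), masses = c(0.01, 1, 100),
#'                     magnitudes = c(10, 30))
#' }
#' @export
delay_surface_swing <- function(laws = swing_laws(),
                                masses = NULL,
                                magnitudes = NULL,
                                config = analysis_config()) {
  masses <- masses %||% config$masses
  magnitudes <- magnitudes %||% config$swing_magnitudes
  stopifnot(length(masses) >= 1, length(magnitudes) >= 1)
  grid <- tidyr::expand_grid(mass_kg = masses, magnitude_deg = magnitudes)
  cells <- purrr::pmap(grid, function(mass_kg, magnitude_deg) {
    pars <- swing_parameters(mass_kg, laws, config)
    tryCatch(
      list(delay = simulate_swing(pars, magnitude_deg, config)$inertial_delay,
           ok = TRUE),
      error = function(e) {
        warning("swing cell failed (M = ", signif(mass_kg, 3), " kg, ",
                signif(magnitude_deg, 3), " deg): ", conditionMessage(e),
                call. = FALSE)
        list(delay = NA_real_, ok = FALSE)
      }
    )
  })
  out <- dplyr::mutate(grid,
                       delay_s = purrr::map_dbl(cells, "delay"),
                       converged = purrr::map_lgl(cells, "ok"))
  structure(out,
            class = c("inertial_delay_surface", class(out)),
            task = "swing",
            complete = all(out$converged))
}
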