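#' Sensorimotor-delay power law
#'
#' Sensorimotor delay — the summed neural and muscular latencies preceding a
#' corrective movement — scales with body mass as `M^0.21`. Its coefficient
#' is not printed alongside the exponent, so it is fixed by the anchor
#' convention: the sensorimotor delay of a 1 kg animal equals that animal's
#' inertial delay at the anchor magnitude (a 30-degree swing movement, or a
#' 0.21 dimensionless-velocity perturbation for the posture task). The
#' inertial delay at the anchor is evaluated from the fitted
#' coefficient-versus-magnitude power law.
#'
#' @param fits A `delay_scaling_fits` tibble from [fit_delay_scaling()].
#' @param anchor_magnitude Anchor magnitude in the task's units; defaults to
#'   the config anchor (30 degrees for swing, 0.21 for posture).
#' @param config An [analysis_config()]; `smd_coefficient` overrides the
#'   anchored coefficient, `smd_exponent` sets the exponent.
#' @return An object of class `sensorimotor_delay_model`: a list with
#'   `coefficient` (s at 1 kg), `exponent`, `task`, and `anchor` (a
#'   description of how the coefficient was fixed).
#' @examples
#' \donttest{
#' fits <- fit_delay_scaling(delay_surface_swing(masses = c(0.01, 1, 100)))
#' smd <- build_sensorimotor_model(fits)
#' sensorimotor_delay(smd, 100) / sensorimotor_delay(smd, 1) # 100^0.21
#' }
#' @export
build_sensorimotor_model <- function(fits, anchor_magnitude = NULL,
                                     config = analysis_config()) {
  stopifnot(inherits(fits, "delay_scaling_fits"))
  task <- attr(fits, "task")
  anchor_magnitude <- anchor_magnitude %||%
    if (task == "swing") config$smd_anchor_deg else config$smd_anchor_vnd
  rng <- range(fits$magnitude)
  if (anchor_magnitude < rng[1] || anchor_magnitude > rng[2]) {
    stop(sprintf("anchor magnitude %.3g outside the fitted range [%.3g, %.3g]",
                 anchor_magnitude, rng[1], rng[2]), call. = FALSE)
  }
  cm <- coefficient_magnitude_law(fits)
  coefficient <- config$smd_coefficient %||%
    predict(cm, anchor_magnitude)
  anchor <- if (is.null(config$smd_coefficient)) {
    sprintf("equals the %s inertial delay at magnitude %.3g for a 1 kg animal",
            task, anchor_magnitude)
  } else {
    "coefficient supplied directly via config$smd_coefficient"
  }
  structure(
    list(coefficient = coefficient, exponent = config$smd_exponent,
         task = task, anchor_magnitude = anchor_magnitude, anchor = anchor),
    class = "sensorimotor_delay_model"
  )
}

#' @rdname build_sensorimotor_model
#' @param model A `sensorimotor_delay_model`.
#' @param mass Body mass, kg (vectorized).
#' @return `sensorimotor_delay()` returns the delay in seconds.
#' @export
sensorimotor_delay <- function(model, mass) {
  stopifnot(inherits(model, "sensorimotor_delay_model"))
  model$coefficient * mass^model$exponent
}

#' @export
print.sensorimotor_delay_model <- function(x, ...) {
  cat(sprintf("<sensorimotor_delay_model> %.4g ms * M^%.3g (%s anchor: %s)\n",
              1e3 * x$coefficient, x$exponent, x$task, x$anchor))
  invisible(x)
}

#' Movement magnitude at which inertial delay equals sensorimotor delay
#'
#' For a given body mass, solves `a(magnitude) * M^b = smd(M)` for the
#' movement magnitude, where `a(magnitude)` is the fitted
#' coefficient-versus-magnitude power law of the task (square-root-like for
#' swing, near-linear for posture) and `b` the task's average exponent.
#' Beyond the crossover, inertia — not sensorimotor latency — dominates the
#' response time.
#'
#' @param fits A `delay_scaling_fits` tibble.
#' @param mass Body mass, kg (vectorized).
#' @param smd A `sensorimotor_delay_model` (defaults to the anchor-convention
#'   model built from `fits`).
#' @param config An [analysis_config()].
#' @param extrapolate Allow solutions outside the simulated magnitude range;
#'   defaults to `config$extrapolate_crossover`.
#' @return Crossover magnitude(s) in the task's units (degrees or
#'   dimensionless velocity).
#' @examples
#' \donttest{
#' fits <- fit_delay_scaling(delay_surface_swing())
#' crossover_magnitude(fits, 1) # = 30 by the anchor construction
#' }
#' @export
crossover_magnitude <- function(fits, mass, smd = NULL,
                                config = analysis_config(),
                                extrapolate = NULL) {
  stopifnot(inherits(fits, "delay_scaling_fits"))
  if (any(mass <= 0)) stop("mass must be positive", call. = FALSE)
  smd <- smd %||% build_sensorimotor_model(fits, config = config)
  extrapolate <- extrapolate %||% config$extrapolate_crossover
  cm <- coefficient_magnitude_law(fits)
  b <- average_exponent(fits)
  # c * mag^p * M^b = A * M^es  =>  mag = (A / c)^(1/p) * M^((es - b)/p)
  mag <- (smd$coefficient / cm$coefficient *
            mass^(smd$exponent - b))^(1 / cm$exponent)
  rng <- range(fits$magnitude)
  out_of_range <- mag < rng[1] | mag > rng[2]
  if (any(out_of_range) && !extrapolate) {
    stop(sprintf(
      "crossover magnitude outside the simulated range [%.3g, %.3g] for mass(es) %s; set extrapolate = TRUE to evaluate the fitted law beyond it",
      rng[1], rng[2],
      paste(signif(mass[out_of_range], 3), collapse = ", ")), call. = FALSE)
  }
  mag
}

#' Power law of crossover magnitude against body mass
#'
#' Fits `crossover = a * M^b` over a mass grid. Both tasks yield exponents
#' near -0.14: larger animals reach the inertia-dominated regime at smaller
#' movements.
#'
#' @inheritParams crossover_magnitude
#' @param masses Body masses for the fit, kg.
#' @return An object of class `crossover_law`: a list with `task`,
#'   `coefficient` (magnitude at 1 kg), `exponent`, and the underlying
#'   `power_law_fit`.
#' @export
fit_crossover_law <- function(fits, smd = NULL, masses = NULL,
                              config = analysis_config()) {
  masses <- masses %||% config$masses
  smd <- smd %||% build_sensorimotor_model(fits, config = config)
  mags <- crossover_magnitude(fits, masses, smd, config, extrapolate = TRUE)
  fit <- fit_power_law(masses, mags)
  structure(
    list(task = attr(fits, "task"), coefficient = fit$coefficient,
         exponent = fit$exponent, fit = fit),
    class = "crossover_law"
  )
}

#' @export
print.crossover_law <- function(x, ...) {
  unit <- if (x$task == "swing") "degrees" else "dimensionless velocity"
  cat(sprintf("<crossover_law> %s: %.3g * M^%.3g %s\n",
              x$task, x$coefficient, x$exponent, unit))
  invisible(x)
}

#' Available movement time
#'
#' Task-relevant time budgets for a corrective movement: swing duration at
#' maximum sprint speed (`0.148 * M^0.13` s), time to fall one leg length,
#' or the natural pendulum period of the leg (the latter two computed from
#' the mean fore/hindlimb length law).
#'
#' @param mass Body mass, kg (vectorized).
#' @param kind One of `"sprint_swing"`, `"fall"`, `"pendulum_period"`.
#' @param laws Scaling-law tibble in the [posture_laws()] schema (supplies
#'   limb lengths for the fall and pendulum kinds).
#' @param config An [analysis_config()].
#' @return Time in seconds.
#' @examples
#' available_movement_time(1, "sprint_swing") # 0.148 s
#' @export
available_movement_time <- function(mass,
                                    kind = c("sprint_swing", "fall",
                                             "pendulum_period"),
                                    laws = posture_laws(),
                                    config = analysis_config()) {
  kind <- match.arg(kind)
  if (any(mass <= 0)) stop("mass must be positive", call. = FALSE)
  if (kind == "sprint_swing") {
    return(config$sprint_swing_coef * mass^config$sprint_swing_exp)
  }
  l_fore <- evaluate_scaling_law(as_scaling_law(laws, "forelimb_length"), mass)
  l_hind <- evaluate_scaling_law(as_scaling_law(laws, "hindlimb_length"), mass)
  leg <- (l_fore + l_hind) / 2
  switch(kind,
         fall = fall_time(leg, config$gravity),
         pendulum_period = pendulum_period(leg, config$gravity))
}

#' Relative response time
#'
#' Response time (sensorimotor delay plus swing-task inertial delay at a
#' fixed movement magnitude) normalized by the swing duration at maximum
#' sprint speed, across a body-mass grid, together with its fitted power
#' law.
#'
#' @param fits A swing-task `delay_scaling_fits` tibble.
#' @param smd A `sensorimotor_delay_model`; defaults to the anchor
#'   convention.
#' @param masses Body masses, kg.
#' @param magnitude Swing movement magnitude, degrees (defaults to the
#'   anchor, 30 degrees, at which the two delay components are equal at
#'   1 kg).
#' @param config An [analysis_config()].
#' @return A tibble with columns `mass_kg`, `sensorimotor_s`, `inertial_s`,
#'   `response_s`, `available_s`, `relative`; the fitted power law of
#'   `relative` against mass is attached as attribute `"law"` (a
#'   `power_law_fit`).
#' @export
relative_response_time <- function(fits, smd = NULL, masses = NULL,
                                   magnitude = NULL,
                                   config = analysis_config()) {
  stopifnot(inherits(fits, "delay_scaling_fits"),
            attr(fits, "task") == "swing")
  masses <- masses %||% config$masses
  smd <- smd %||% build_sensorimotor_model(fits, config = config)
  magnitude <- magnitude %||% config$smd_anchor_deg
  cm <- coefficient_magnitude_law(fits)
  b <- average_exponent(fits)
  inertial <- predict(cm, magnitude) * masses^b
  sensorimotor <- sensorimotor_delay(smd, masses)
  available <- available_movement_time(masses, "sprint_swing", config = config)
  out <- tibble::tibble(
    mass_kg = masses,
    sensorimotor_s = sensorimotor,
    inertial_s = inertial,
    response_s = sensorimotor + inertial,
    available_s = available,
    relative = (sensorimotor + inertial) / available
  )
  attr(out, "law") <- fit_power_law(out$mass_kg, out$relative)
  out
}

#' Sensitivity of the scaling exponent to muscle torque
#'
#' Re-runs a task's delay surface and power-law fits with every muscle
#' torque multiplied by each factor, reporting the average exponent across
#' magnitudes. The exponent is insensitive to even four-fold torque changes,
#' so uncertainty in the absolute torque estimates does not threaten the
#' scaling conclusions.
#'
#' @param laws Scaling-law tibble for the task.
#' @param task `"swing"` or `"posture"`.
#' @param factors Positive torque multipliers (1 is the baseline).
#' @param config An [analysis_config()].
#' @return A tibble with columns `factor` and `average_exponent`.
#' @examples
#' \donttest{
#' torque_sensitivity(swing_laws(), "swing", factors = c(0.5, 1, 4))
#' }
#' @export
torque_sensitivity <- function(laws, task = c("swing", "posture"),
                               factors = c(0.5, 1, 4),
                               config = analysis_config()) {
  task <- match.arg(task)
  if (any(factors <= 0)) stop("factors must be positive", call. = FALSE)
  exps <- purrr::map_dbl(factors, function(f) {
    cfg <- config
    cfg$torque_factor <- config$torque_factor * f
    surface <- if (task == "swing") {
      delay_surface_swing(laws, config = cfg)
    } else {
      delay_surface_posture(laws, config = cfg)
    }
    average_exponent(fit_delay_scaling(surface))
  })
  tibble::tibble(factor = factors, average_exponent = exps)
}
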