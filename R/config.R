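#' Analysis configuration
#'
#' Collects every tunable of the baseline analysis in one serializable list.
#' The defaults reproduce the published analysis: seven body masses
#' log-spaced from 1 g to 10 t, swing movement magnitudes of 1-60 degrees
#' (total excursion), posture perturbations of 0.01-0.49 dimensionless
#' velocity, muscle density 1060 kg/m^3, isometric stress 20 N/cm^2
#' (2e5 N/m^2), gravity 9.81 m/s^2, and a sensorimotor delay scaling as
#' M^0.21 anchored so that it equals the 30-degree swing inertial delay at
#' 1 kg.
#'
#' @param gravity Gravitational acceleration, m/s^2.
#' @param muscle_density Muscle density, kg/m^3.
#' @param isometric_stress Muscle isometric stress, N/m^2 (20 N/cm^2 default).
#' @param torque_factor Multiplier applied to every muscle torque (sensitivity
#'   analyses); 1 is the baseline.
#' @param masses Body-mass grid, kg.
#' @param swing_magnitudes Swing movement magnitudes, degrees of total
#'   excursion (twice the initial clockwise angle).
#' @param vnd_grid Posture perturbations, dimensionless velocity.
#' @param rtol,atol Integrator relative/absolute tolerances.
#' @param swing_gravity One of `"restoring"`, `"destabilizing"`, `"off"`:
#'   orientation of the gravity term in the swing pendulum (the published
#'   equation's sign is ambiguous; only the restoring reading reproduces the
#'   printed coefficients).
#' @param mc_draws Monte Carlo draw count (the published analysis used 10,000;
#'   scaled-down runs use 500).
#' @param mc_df Degrees of freedom for the t-distributions used to sample
#'   scaling parameters from their confidence intervals.
#' @param smd_exponent Body-mass exponent of the sensorimotor delay law.
#' @param smd_anchor_deg Swing magnitude (degrees) at which sensorimotor delay
#'   equals inertial delay for a 1 kg animal; fixes the law's coefficient.
#' @param smd_anchor_vnd Posture analogue of the anchor (dimensionless
#'   velocity).
#' @param smd_coefficient Optional override of the sensorimotor-delay
#'   coefficient (s at 1 kg); `NULL` uses the anchor convention.
#' @param sprint_swing_coef,sprint_swing_exp Sprint swing-duration law:
#'   duration in s at 1 kg and its body-mass exponent (0.148 s, 0.13).
#' @param extrapolate_crossover Allow crossover magnitudes outside the
#'   simulated magnitude range to be computed from the fitted power laws.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(gravity = 9.81,
                            muscle_density = 1060,
                            isometric_stress = 20e4,
                            torque_factor = 1,
                            masses = mass_grid(),
                            swing_magnitudes = log_spaced(1, 60, 10),
                            vnd_grid = log_spaced(0.01, 0.49, 15),
                            rtol = 1e-8,
                            atol = 1e-10,
                            swing_gravity = c("restoring", "destabilizing", "off"),
                            mc_draws = 10000L,
                            mc_df = 20,
                            smd_exponent = 0.21,
                            smd_anchor_deg = 30,
                            smd_anchor_vnd = 0.21,
                            smd_coefficient = NULL,
                            sprint_swing_coef = 0.148,
                            sprint_swing_exp = 0.13,
                            extrapolate_crossover = FALSE) {
  swing_gravity <- match.arg(swing_gravity)
  stopifnot(gravity >= 0, muscle_density > 0, isometric_stress > 0,
            torque_factor > 0, rtol > 0, atol > 0)
  structure(
    list(gravity = gravity,
         muscle_density = muscle_density,
         isometric_stress = isometric_stress,
         torque_factor = torque_factor,
         masses = masses,
         swing_magnitudes = swing_magnitudes,
         vnd_grid = vnd_grid,
         rtol = rtol,
         atol = atol,
         swing_gravity = swing_gravity,
         mc_draws = as.integer(mc_draws),
         mc_df = mc_df,
         smd_exponent = smd_exponent,
         smd_anchor_deg = smd_anchor_deg,
         smd_anchor_vnd = smd_anchor_vnd,
         smd_coefficient = smd_coefficient,
         sprint_swing_coef = sprint_swing_coef,
         sprint_swing_exp = sprint_swing_exp,
         extrapolate_crossover = extrapolate_crossover),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  masses: %d from %.3g to %.3g kg\n",
              length(x$masses), min(x$masses), max(x$masses)))
  cat(sprintf("  swing magnitudes: %d from %.3g to %.3g deg\n",
              length(x$swing_magnitudes), min(x$swing_magnitudes),
              max(x$swing_magnitudes)))
  cat(sprintf("  posture perturbations: %d from %.3g to %.3g v_ND\n",
              length(x$vnd_grid), min(x$vnd_grid), max(x$vnd_grid)))
  cat(sprintf("  g = %.3g m/s^2, stress = %.3g N/m^2, density = %.4g kg/m^3, torque x%.3g\n",
              x$gravity, x$isometric_stress, x$muscle_density, x$torque_factor))
  cat(sprintf("  integrator rtol %.1e / atol %.1e, swing gravity %s\n",
              x$rtol, x$atol, x$swing_gravity))
  invisible(x)
}

#' Logarithmically spaced grid
#'
#' @param from,to Positive endpoints (inclusive).
#' @param n Number of points.
#' @return Numeric vector geometrically spaced between the endpoints.
#' @export
log_spaced <- function(from, to, n) {
  stopifnot(from > 0, to > 0, n >= 2)
  10^seq(log10(from), log10(to), length.out = n)
}

#' Body-mass grid
#'
#' Geometrically spaced body masses spanning the terrestrial-mammal size
#' range; the default reproduces the seven masses from one gram to ten tons
#' used throughout the analysis.
#'
#' @param n Number of masses (>= 2).
#' @param m_min,m_max Range endpoints in kg, inclusive.
#' @return Numeric vector of masses in kg.
#' @examples
#' mass_grid() # 1e-3 ... 1e4 kg, ratio 10^(7/6)
#' @export
mass_grid <- function(n = 7, m_min = 1e-3, m_max = 1e4) {
  if (n < 2) stop("mass grid needs at least 2 points", call. = FALSE)
  if (!(m_min > 0 && m_max > m_min)) {
    stop("mass grid requires 0 < m_min < m_max", call. = FALSE)
  }
  log_spaced(m_min, m_max, n)
}
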