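#' Muscle groups and the muscle-torque chain
#'
#' A muscle group bundles the three scaling laws (muscle mass, fascicle
#' length, moment arm) and the two constants (density, isometric stress)
#' needed to turn body mass into maximal joint torque. Maximal force is
#' isometric stress times physiological cross-sectional area (PCSA), where
#' PCSA is muscle volume (mass / density) divided by fascicle length; torque
#' is force times moment arm, times `leg_multiplier` legs acting together
#' (1 for the swing task's triceps, 4 for the posture task's ankle extensors).
#'
#' @param mass_law,length_law,moment_arm_law [scaling_law()] objects for
#'   muscle mass (kg), fascicle length (m), and moment arm (m).
#' @param density Muscle density, kg/m^3.
#' @param isometric_stress Isometric stress, N/m^2.
#' @param leg_multiplier Number of legs whose muscle torque sums (1 or 4 in
#'   the baseline tasks).
#' @return An object of class `muscle_group`.
#' @export
muscle_group <- function(mass_law, length_law, moment_arm_law,
                         density = 1060, isometric_stress = 20e4,
                         leg_multiplier = 1L) {
  stopifnot(inherits(mass_law, "scaling_law"),
            inherits(length_law, "scaling_law"),
            inherits(moment_arm_law, "scaling_law"))
  if (density <= 0 || isometric_stress <= 0) {
    stop("density and isometric stress must be positive", call. = FALSE)
  }
  if (leg_multiplier < 1) stop("leg_multiplier must be >= 1", call. = FALSE)
  structure(
    list(mass_law = mass_law, length_law = length_law,
         moment_arm_law = moment_arm_law, density = density,
         isometric_stress = isometric_stress,
         leg_multiplier = as.integer(leg_multiplier)),
    class = "muscle_group"
  )
}

#' @rdname muscle_group
#' @param laws Scaling-law tibble to draw from (defaults to the packaged
#'   tables).
#' @param config An [analysis_config()] supplying density and stress.
#' @export
triceps_group <- function(laws = swing_laws(), config = analysis_config()) {
  muscle_group(as_scaling_law(laws, "triceps_mass"),
               as_scaling_law(laws, "triceps_length"),
               as_scaling_law(laws, "triceps_moment_arm"),
               density = config$muscle_density,
               isometric_stress = config$isometric_stress,
               leg_multiplier = 1L)
}

#' @rdname muscle_group
#' @export
ankle_extensor_group <- function(laws = posture_laws(),
                                 config = analysis_config()) {
  muscle_group(as_scaling_law(laws, "ankle_extensor_mass"),
               as_scaling_law(laws, "ankle_extensor_length"),
               as_scaling_law(laws, "ankle_extensor_moment_arm"),
               density = config$muscle_density,
               isometric_stress = config$isometric_stress,
               leg_multiplier = 4L)
}

#' Maximal isometric muscle force
#'
#' @param group A [muscle_group()].
#' @param mass Body mass, kg.
#' @return Force in N: `stress * (muscle_mass / density) / fascicle_length`.
#' @examples
#' muscle_force(triceps_group(), 1) # ~62.6 N
#' @export
muscle_force <- function(group, mass) {
  stopifnot(inherits(group, "muscle_group"))
  m_musc <- evaluate_scaling_law(group$mass_law, mass)
  l_musc <- evaluate_scaling_law(group$length_law, mass)
  if (any(l_musc <= 0)) stop("muscle length must be positive", call. = FALSE)
  pcsa <- (m_musc / group$density) / l_musc
  group$isometric_stress * pcsa
}

#' Maximal muscle torque
#'
#' Force times moment arm, summed over `leg_multiplier` legs.
#'
#' @inheritParams muscle_force
#' @return Torque in N m.
#' @examples
#' muscle_torque(ankle_extensor_group(), 1) # ~3.41 N m (4 legs)
#' @export
muscle_torque <- function(group, mass) {
  muscle_force(group, mass) *
    evaluate_scaling_law(group$moment_arm_law, mass) *
    group$leg_multiplier
}

#' Task parameters for one animal size
#'
#' `swing_parameters()` evaluates the forelimb inertial laws and the triceps
#' torque chain at a body mass, returning everything the swing-task pendulum
#' needs. `posture_parameters()` does the same for the inverted-pendulum
#' posture task: limb length is the mean of the fore- and hindlimb laws and
#' the torque is four ankle-extensor groups acting together.
#'
#' @param mass Body mass, kg (scalar, positive).
#' @param laws Scaling-law tibble ([swing_laws()] or [posture_laws()] schema).
#' @param config An [analysis_config()]; supplies gravity, muscle constants,
#'   and the torque multiplier.
#' @return A one-row tibble of class `swing_parameters` with columns
#'   `body_mass, limb_mass, com_length, moment_of_inertia, muscle_torque,
#'   gravity` (respectively `posture_parameters` with `body_mass, limb_length,
#'   muscle_torque, gravity`), all strict SI.
#' @examples
#' swing_parameters(1)
#' posture_parameters(1)
#' @export
swing_parameters <- function(mass, laws = swing_laws(),
                             config = analysis_config()) {
  check_scalar_mass(mass)
  torque <- muscle_torque(triceps_group(laws, config), mass) *
    config$torque_factor
  out <- tibble::tibble(
    body_mass = mass,
    limb_mass = evaluate_scaling_law(as_scaling_law(laws, "forelimb_mass"), mass),
    com_length = evaluate_scaling_law(as_scaling_law(laws, "forelimb_com_length"), mass),
    moment_of_inertia = evaluate_scaling_law(as_scaling_law(laws, "forelimb_moi"), mass),
    muscle_torque = torque,
    gravity = config$gravity
  )
  stopifnot(out$limb_mass > 0, out$com_length > 0,
            out$moment_of_inertia > 0, out$muscle_torque > 0)
  class(out) <- c("swing_parameters", class(out))
  out
}

#' @rdname swing_parameters
#' @export
posture_parameters <- function(mass, laws = posture_laws(),
                               config = analysis_config()) {
  check_scalar_mass(mass)
  l_fore <- evaluate_scaling_law(as_scaling_law(laws, "forelimb_length"), mass)
  l_hind <- evaluate_scaling_law(as_scaling_law(laws, "hindlimb_length"), mass)
  torque <- muscle_torque(ankle_extensor_group(laws, config), mass) *
    config$torque_factor
  out <- tibble::tibble(
    body_mass = mass,
    limb_length = (l_fore + l_hind) / 2,
    muscle_torque = torque,
    gravity = config$gravity
  )
  class(out) <- c("posture_parameters", class(out))
  out
}

check_scalar_mass <- function(mass) {
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0) {
    stop("mass must be a single positive number (kg)", call. = FALSE)
  }
  invisible(mass)
}
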