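# Configuration objects for the grasp-and-lift simulator.
#
# Defaults reproduce the study apparatus: a gated-ramp differential force
# controller (close 0.12 m/s, ramp 5 N/s, 0-15 N), a force sensor linear over
# 0-10 N sampled at 1 kHz, 240 Hz motion tracking, and two low-friction test
# objects (150 g and 300 g, 55 mm contact diameter).

#' Object specification
#'
#' Physical description of the object being grasped and lifted. The study used
#' two upward-tapered beakers covered in low-friction cellulose film: a
#' lightweight one (150 g) and a heavy one (300 g), both 55 mm in diameter at
#' the point of contact.
#'
#' @param name Either a preset name (`"heavy"`, `"light"`) or a custom label.
#' @param mass Object mass in kg. Required unless a preset name is given.
#' @param contact_diameter Diameter at the grip contact point, metres.
#' @param friction_coefficient Finger-object Coulomb friction coefficient
#'   (dimensionless). The film's friction was not measured; 0.4 is a plausible
#'   low-friction default and is configurable.
#' @param baseline_height Resting height of the object base, metres (z-up).
#'
#' @return An object of class `object_spec`.
#' @examples
#' object_spec("heavy")
#' object_spec("custom", mass = 0.2)
#' @export
object_spec <- function(name = c("heavy", "light"),
                        mass = NULL,
                        contact_diameter = 0.055,
                        friction_coefficient = 0.4,
                        baseline_height = 0) {
  if (is.null(mass)) {
    name <- match.arg(name)
    mass <- switch(name, heavy = 0.300, light = 0.150)
  } else {
    name <- as.character(name)[1L]
  }
  assert_scalar_num(mass, "mass", 0, strict = TRUE)
  assert_scalar_num(contact_diameter, "contact_diameter", 0, strict = TRUE)
  assert_scalar_num(friction_coefficient, "friction_coefficient", 0, strict = TRUE)
  assert_scalar_num(baseline_height, "baseline_height")
  structure(
    list(name = name, mass = mass, contact_diameter = contact_diameter,
         friction_coefficient = friction_coefficient,
         baseline_height = baseline_height),
    class = "object_spec"
  )
}

#' Gated-ramp controller configuration
#'
#' The hand closes/opens at a constant speed while the corresponding binary
#' control signal is held; once contact is made, grip force ramps up at a
#' constant rate for as long as the flexor signal is held, saturating at
#' `force_max`.
#'
#' @param close_speed Hand closing speed while the flexor signal is on, m/s.
#' @param open_speed Hand opening speed while the extensor signal is on, m/s.
#' @param ramp_rate Grip-force ramp rate after contact, N/s.
#' @param force_max Saturation grip force, N.
#' @param control_dt Controller time step (zero-order hold), s.
#' @param contact_preload Small grip force registered the instant the fingers
#'   close on the object, before the force ramp engages, N. This is what makes
#'   the force-threshold segmentation land on the moment of contact even when
#'   a random pre-ramp delay holds the ramp off.
#'
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(close_speed = 0.12,
                              open_speed = 0.12,
                              ramp_rate = 5,
                              force_max = 15,
                              control_dt = 0.001,
                              contact_preload = 0.3) {
  assert_scalar_num(close_speed, "close_speed", 0, strict = TRUE)
  assert_scalar_num(open_speed, "open_speed", 0, strict = TRUE)
  assert_scalar_num(ramp_rate, "ramp_rate", 0, strict = TRUE)
  assert_scalar_num(force_max, "force_max", 0, strict = TRUE)
  assert_scalar_num(control_dt, "control_dt", 0, strict = TRUE)
  assert_scalar_num(contact_preload, "contact_preload", 0)
  if (contact_preload >= force_max) {
    stopf("invariant violated: contact_preload < force_max required")
  }
  structure(
    list(close_speed = close_speed, open_speed = open_speed,
         ramp_rate = ramp_rate, force_max = force_max,
         control_dt = control_dt, contact_preload = contact_preload),
    class = "controller_config"
  )
}

#' Random controller-delay specification
#'
#' Temporal feedforward uncertainty is injected as random dead times in the
#' hand controller, one independent uniform draw per insertion point: before
#' the onset of movement and before the onset of the force ramp. The study
#' drew delays uniformly from 0 to 1.5 s.
#'
#' @param enabled Logical; if `FALSE` no delays are injected.
#' @param low,high Bounds of the uniform delay distribution, seconds.
#' @param insertion_points Character subset of
#'   `c("pre_movement", "pre_ramp")`.
#'
#' @return An object of class `delay_spec`.
#' @export
delay_spec <- function(enabled = FALSE, low = 0, high = 1.5,
                       insertion_points = c("pre_movement", "pre_ramp")) {
  stopifnot(is.logical(enabled), length(enabled) == 1L, !is.na(enabled))
  assert_scalar_num(low, "low", 0)
  assert_scalar_num(high, "high")
  if (low > high) stopf("invariant violated: 0 <= low <= high required")
  insertion_points <- match.arg(insertion_points,
                                c("pre_movement", "pre_ramp"),
                                several.ok = TRUE)
  structure(
    list(enabled = enabled, low = low, high = high,
         insertion_points = insertion_points),
    class = "delay_spec"
  )
}

#' Sensor configuration
#'
#' The grip-force sensor is linear over `0` to `force_linear_max` newtons and
#' sampled at `force_rate`; forces above the linear range saturate (clip).
#' Positions are tracked at `position_rate`. Optional additive Gaussian
#' measurement noise on each channel.
#'
#' @param force_rate Force sampling rate, Hz (study: 1000).
#' @param position_rate Position sampling rate, Hz (study: 240).
#' @param force_linear_max Upper end of the force sensor's linear range, N
#'   (study: 10).
#' @param force_noise_sd Gaussian force measurement noise SD, N.
#' @param position_noise_sd Gaussian position measurement noise SD, m.
#'
#' @return An object of class `sensor_config`.
#' @export
sensor_config <- function(force_rate = 1000, position_rate = 240,
                          force_linear_max = 10,
                          force_noise_sd = 0, position_noise_sd = 0) {
  assert_scalar_num(force_rate, "force_rate", 0, strict = TRUE)
  assert_scalar_num(position_rate, "position_rate", 0, strict = TRUE)
  assert_scalar_num(force_linear_max, "force_linear_max", 0, strict = TRUE)
  assert_scalar_num(force_noise_sd, "force_noise_sd", 0)
  assert_scalar_num(position_noise_sd, "position_noise_sd", 0)
  structure(
    list(force_rate = force_rate, position_rate = position_rate,
         force_linear_max = force_linear_max,
         force_noise_sd = force_noise_sd,
         position_noise_sd = position_noise_sd),
    class = "sensor_config"
  )
}

#' Simulated subject policy
#'
#' Minimal model of the human in the loop. The subject plans a flexor hold
#' duration per object-weight belief (the feedforward component) and, when a
#' feedback channel is available, corrects the flexor release time toward the
#' moment the perceived grip force reaches the planned target force (the
#' feedback component). Perception of force is corrupted by Gaussian noise.
#'
#' @param planned_ramp_duration Named numeric vector of planned flexor hold
#'   durations (seconds after contact), one entry per object name the subject
#'   may encounter (e.g. `c(heavy = 1.1, light = 0.7)`).
#' @param feedback_gain Fraction (0-1) of the feedforward timing error
#'   corrected per trial when a feedback channel is present; 0 disables
#'   within-trial correction.
#' @param perceptual_noise_sd SD of the perceived-force error, N. With several
#'   feedback channels available the effective SD shrinks as
#'   `perceptual_noise_sd / sqrt(n_channels)`.
#' @param reaction_time Lag between the perceived force crossing the target
#'   and the flexor actually releasing, s.
#' @param feedback_channels Character subset of `c("visual", "vibrotactile")`;
#'   empty means pure feedforward control within the trial.
#' @param early_release_prob Probability that the subject accidentally relaxes
#'   the grip mid-hold, causing the object to drop. Mishap plumbing used to
#'   exercise the drop detector; 0 by default.
#'
#' @return An object of class `subject_policy`.
#' @export
subject_policy <- function(planned_ramp_duration = c(heavy = 1.1, light = 0.7),
                           feedback_gain = 0,
                           perceptual_noise_sd = 0.3,
                           reaction_time = 0.1,
                           feedback_channels = character(),
                           early_release_prob = 0) {
  if (!is.numeric(planned_ramp_duration) || is.null(names(planned_ramp_duration)) ||
      any(!nzchar(names(planned_ramp_duration)))) {
    stopf("'planned_ramp_duration' must be a named numeric vector (seconds per object name)")
  }
  if (any(planned_ramp_duration < 0)) {
    stopf("invariant violated: planned_ramp_duration >= 0 required")
  }
  assert_scalar_num(feedback_gain, "feedback_gain", 0)
  assert_scalar_num(perceptual_noise_sd, "perceptual_noise_sd", 0)
  assert_scalar_num(reaction_time, "reaction_time", 0)
  assert_scalar_num(early_release_prob, "early_release_prob", 0)
  if (early_release_prob > 1) stopf("'early_release_prob' must lie in [0, 1]")
  if (length(feedback_channels)) {
    feedback_channels <- match.arg(feedback_channels,
                                   c("visual", "vibrotactile"),
                                   several.ok = TRUE)
  }
  structure(
    list(planned_ramp_duration = planned_ramp_duration,
         feedback_gain = feedback_gain,
         perceptual_noise_sd = perceptual_noise_sd,
         reaction_time = reaction_time,
         feedback_channels = as.character(feedback_channels),
         early_release_prob = early_release_prob,
         learning = list()),
    class = "subject_policy"
  )
}

#' @export
print.object_spec <- function(x, ...) {
  cat(sprintf("<object_spec '%s'> mass %.3f kg, contact diameter %.0f mm, mu %.2f\n",
              x$name, x$mass, x$contact_diameter * 1000, x$friction_coefficient))
  invisible(x)
}

#' @export
print.subject_policy <- function(x, ...) {
  ch <- if (length(x$feedback_channels)) paste(x$feedback_channels, collapse = "+") else "none"
  cat(sprintf("<subject_policy> planned hold: %s; feedback: %s (gain %.2f)\n",
              paste(sprintf("%s=%.2fs", names(x$planned_ramp_duration),
                            x$planned_ramp_duration), collapse = ", "),
              ch, x$feedback_gain))
  invisible(x)
}
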