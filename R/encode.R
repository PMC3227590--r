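# Spatially encoded vibrotactile force display.
#
# Grip force maps linearly onto a stimulation locus along an 8-motor array
# spanning the palmar forearm (display units 0 = wrist, 255 = elbow; 0 N at
# the wrist, 10 N and above at the elbow). Loci between motors are rendered by
# co-stimulating the two neighbouring motors with linearly crossfaded duty
# cycles ("between-motor" sensations). An uncorrelated random stimulus
# generator provides the control condition: random locations, frequencies and
# durations carrying no force information.

#' Tactor array configuration
#'
#' @param n_motors Number of motors (study: 8).
#' @param motor_positions Motor loci in display units on `[0, 255]`, wrist to
#'   elbow, strictly increasing; default equally spaced.
#' @param frequency_range Achievable stimulation frequencies, Hz.
#' @param pulse_width_range Achievable pulse widths, s.
#' @param force_range Force span mapped onto the display, N.
#' @param duration_range Random-stimulus duration band, s.
#' @return An object of class `tactor_array_config`.
#' @export
tactor_array_config <- function(n_motors = 8,
                                motor_positions = seq(0, 255, length.out = n_motors),
                                frequency_range = c(2, 200),
                                pulse_width_range = c(5e-4, 0.064),
                                force_range = c(0, 10),
                                duration_range = c(0.1, 1.0)) {
  assert_scalar_num(n_motors, "n_motors", 1)
  if (length(motor_positions) != n_motors ||
      is.unsorted(motor_positions, strictly = TRUE)) {
    stopf("motor_positions must be %d strictly increasing values", n_motors)
  }
  for (rng in list(frequency_range, pulse_width_range, force_range, duration_range)) {
    if (length(rng) != 2L || rng[1L] > rng[2L]) stopf("ranges must be valid (lo <= hi)")
  }
  structure(list(n_motors = as.integer(n_motors),
                 motor_positions = motor_positions,
                 frequency_range = frequency_range,
                 pulse_width_range = pulse_width_range,
                 force_range = force_range,
                 duration_range = duration_range),
            class = "tactor_array_config")
}

#' Map grip force to a display location
#'
#' Linear map of the force, clipped into `force_range`, onto display units
#' `[0, 255]`: 0 N lands at the wrist end, forces at or above the top of the
#' range (10 N) at the elbow end. Clipping, not wrapping: the controller can
#' reach 15 N but the display saturates.
#'
#' @param force Grip force, N (vectorised); negative values rejected.
#' @param cfg A [tactor_array_config()].
#' @return Display location(s) on `[0, 255]`.
#' @examples
#' force_to_location(c(0, 5, 10, 15))
#' @export
force_to_location <- function(force, cfg = tactor_array_config()) {
  if (any(force < 0)) stopf("negative force rejected")
  fr <- cfg$force_range
  frac <- (pmin(pmax(force, fr[1L]), fr[2L]) - fr[1L]) / (fr[2L] - fr[1L])
  frac * 255
}

#' Render a display location as a motor stimulation pattern
#'
#' A location exactly on a motor activates that motor alone at full duty;
#' between two adjacent motors both are active with duty cycles linearly
#' weighted by proximity (weights summing to one). Non-adjacent motor pairs
#' are never co-activated in force-encoding mode.
#'
#' @param location Display location on `[0, 255]`.
#' @param cfg A [tactor_array_config()].
#' @param frequency Stimulation frequency, Hz.
#' @param duration Stimulus duration, s.
#' @param onset Stimulus onset time, s.
#' @return An object of class `stimulus_pattern`: data frame with columns
#'   `motor_index`, `position`, `duty_cycle`, `frequency_hz`, plus `onset` and
#'   `duration` attributes.
#' @export
location_to_pattern <- function(location, cfg = tactor_array_config(),
                                frequency = 100, duration = 0.1, onset = 0) {
  assert_scalar_num(location, "location")
  if (location < 0 || location > 255) {
    stopf("location %g outside the display range [0, 255]", location)
  }
  if (frequency < cfg$frequency_range[1L] || frequency > cfg$frequency_range[2L]) {
    stopf("frequency %g Hz outside the achievable range [%g, %g]",
          frequency, cfg$frequency_range[1L], cfg$frequency_range[2L])
  }
  pos <- cfg$motor_positions
  loc <- min(max(location, pos[1L]), pos[length(pos)])
  hi <- which(pos >= loc)[1L]
  if (pos[hi] == loc) {
    idx <- hi
    duty <- 1
  } else {
    lo <- hi - 1L
    w_hi <- (loc - pos[lo]) / (pos[hi] - pos[lo])
    idx <- c(lo, hi)
    duty <- c(1 - w_hi, w_hi)
  }
  out <- data.frame(motor_index = idx, position = pos[idx], duty_cycle = duty,
                    frequency_hz = frequency)
  attr(out, "onset") <- onset
  attr(out, "duration") <- duration
  class(out) <- c("stimulus_pattern", "data.frame")
  out
}

#' Duty-weighted centroid of a stimulation pattern
#'
#' Inverse of [location_to_pattern()]: the duty-cycle-weighted mean of the
#' active motor positions recovers the encoded display location exactly.
#'
#' @param pattern A `stimulus_pattern`.
#' @return Display location, display units.
#' @export
pattern_centroid <- function(pattern) {
  stopifnot(inherits(pattern, "stimulus_pattern"))
  sum(pattern$position * pattern$duty_cycle) / sum(pattern$duty_cycle)
}

#' Uncorrelated random stimulus (control condition)
#'
#' Generates the random vibrotactile stimuli of the control condition:
#' location uniform over the display, frequency uniform over the achievable
#' range, duration uniform over `cfg$duration_range`, all independent of any
#' force signal.
#'
#' @param cfg A [tactor_array_config()].
#' @param seed Integer seed.
#' @param onset Stimulus onset time, s.
#' @return A `stimulus_pattern`.
#' @export
random_stimulus <- function(cfg = tactor_array_config(), seed = NULL, onset = 0) {
  draws <- with_seed(seed, stats::runif(3))
  location <- draws[1L] * 255
  frequency <- cfg$frequency_range[1L] +
    draws[2L] * diff(cfg$frequency_range)
  duration <- cfg$duration_range[1L] +
    draws[3L] * diff(cfg$duration_range)
  location_to_pattern(location, cfg, frequency = frequency,
                      duration = duration, onset = onset)
}

#' Encode a force trace as a motor pattern log
#'
#' Maps every force sample through [force_to_location()] and
#' [location_to_pattern()], producing the long-format pattern log
#' (`time_s, motor_index, duty_cycle, frequency_hz`).
#'
#' @param force_trace Data frame with columns `time` and `force`.
#' @param cfg A [tactor_array_config()].
#' @param frequency Stimulation frequency used for force encoding, Hz.
#' @return Data frame with one row per active motor per sample.
#' @export
encode_force_trace <- function(force_trace, cfg = tactor_array_config(),
                               frequency = 100) {
  stopifnot(is.data.frame(force_trace),
            all(c("time", "force") %in% names(force_trace)))
  rows <- lapply(seq_len(nrow(force_trace)), function(i) {
    p <- location_to_pattern(force_to_location(force_trace$force[i], cfg),
                             cfg, frequency = frequency)
    data.frame(time_s = force_trace$time[i], motor_index = p$motor_index,
               duty_cycle = p$duty_cycle, frequency_hz = p$frequency_hz)
  })
  do.call(rbind, rows)
}
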