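# Closed-loop grasp-and-lift trial simulator.
#
# A trial follows the canonical sequence: reach/close -> contact -> force ramp
# -> lift -> hold -> replace -> release. The hand is driven by a gated-ramp
# controller; the simulated subject times the flexor release either purely by
# feedforward planning or with feedback correction from perceived grip force.
# Random dead times can be injected before movement onset and before the force
# ramp, emulating controller unpredictability.
#
# Failure episodes are stylised so that each ground-truth event kind carries an
# unambiguous kinematic signature for the rule-based detector:
#   * failed lift - grip below the 1 N stable-grasp level; the hand completes
#     the lift while the object never moves,
#   * slip        - the friction cone is violated during the lift; the object's
#     upward velocity decays gently (1.5 m/s^2) and it is left behind, so the
#     relative velocity exceeds 0.05 m/s while the relative acceleration stays
#     far below the 5 m/s^2 drop criterion,
#   * drop        - the object leaves the grasp mid-hold and free-falls (9.81
#     m/s^2 relative acceleration) while the grip-force reading is still above
#     1 N for a short interval, as when an object slides out of a maintained
#     squeeze.

GRAVITY <- 9.81

# fixed kinematic constants of the stylised trial (seconds / metres)
.sim_const <- list(
  initial_aperture = 0.10,  # hand opening at trial start
  settle = 0.2,             # pause between flexor release and lift onset
  lift_amplitude = 0.1,     # lift height
  lift_duration = 1.0,
  hold_duration = 0.5,
  replace_duration = 1.0,
  slip_decel = 1.5,         # object deceleration during a slip episode, m/s^2
  release_decay = 20,       # grip-force decay rate on extensor opening, N/s
  drop_grip_hold = 0.15,    # time the grip reading persists after a drop, s
  thumb_grasp_height = 0.02 # thumb-tip height above object base at grasp
)

#' Two-finger friction-cone slip check
#'
#' For an opposition grip between thumb and forefinger, the grasp holds when
#' the total friction force available at the two contacts exceeds the load:
#' `2 * friction_coefficient * grip_force >= load_force` (closed boundary).
#'
#' @param grip_force Grip (normal) force, N. Vectorised.
#' @param load_force Load force (object weight plus inertial load), N.
#' @param friction_coefficient Coulomb friction coefficient.
#' @return Character vector, `"stable"` or `"slipping"`.
#' @examples
#' slip_check(3, 1.47, 0.4)
#' @export
slip_check <- function(grip_force, load_force, friction_coefficient) {
  if (any(grip_force < 0)) stopf("negative grip_force rejected")
  if (any(load_force < 0)) stopf("negative load_force rejected")
  assert_scalar_num(friction_coefficient, "friction_coefficient", 0, strict = TRUE)
  ifelse(2 * friction_coefficient * grip_force >= load_force, "stable", "slipping")
}

# Draw one uniform delay per insertion point. Internal core shared by
# inject_delays() and simulate_trial().
#' @noRd
draw_delays <- function(delays, seed) {
  pts <- delays$insertion_points
  if (!delays$enabled || !length(pts)) {
    return(data.frame(insertion_point = character(), duration = numeric(),
                      stringsAsFactors = FALSE))
  }
  d <- with_seed(seed, stats::runif(length(pts), delays$low, delays$high))
  data.frame(insertion_point = pts, duration = d, stringsAsFactors = FALSE)
}

#' Inject random delays into a control-signal stream
#'
#' Draws one independent uniform delay per insertion point of `delays` and
#' shifts every sample at or after the corresponding insertion time by that
#' amount (cumulatively, in insertion-time order). The draws are returned
#' exactly as recorded, so the total time shift of the stream tail equals the
#' sum of the recorded durations.
#'
#' @param signal A data frame with a `time` column (strictly increasing).
#' @param delays A [delay_spec()].
#' @param seed Integer seed for the delay draws.
#' @param insertion_times Named numeric vector giving the stream time at which
#'   each insertion point acts; names must cover `delays$insertion_points`.
#'   Defaults to the stream start for `pre_movement` and the stream midpoint
#'   for `pre_ramp`.
#' @return A list with elements `signal` (the delayed stream) and `records`
#'   (data frame `insertion_point`, `time`, `duration`).
#' @export
inject_delays <- function(signal, delays, seed = NULL, insertion_times = NULL) {
  if (!is.data.frame(signal) || !"time" %in% names(signal)) {
    stopf("'signal' must be a data frame with a 'time' column")
  }
  if (is.unsorted(signal$time, strictly = TRUE)) {
    stopf("signal times must be strictly increasing")
  }
  if (!inherits(delays, "delay_spec")) stopf("'delays' must be a delay_spec")
  if (!delays$enabled) {
    return(list(signal = signal,
                records = data.frame(insertion_point = character(),
                                     time = numeric(), duration = numeric(),
                                     stringsAsFactors = FALSE)))
  }
  pts <- delays$insertion_points
  if (is.null(insertion_times)) {
    insertion_times <- c(pre_movement = min(signal$time),
                         pre_ramp = stats::median(signal$time))[pts]
  }
  if (!all(pts %in% names(insertion_times))) {
    stopf("insertion_times must name every insertion point: %s",
          paste(pts, collapse = ", "))
  }
  rec <- draw_delays(delays, seed)
  rec$time <- as.numeric(insertion_times[rec$insertion_point])
  rec <- rec[order(rec$time), c("insertion_point", "time", "duration")]
  out <- signal
  shift <- 0
  for (k in seq_len(nrow(rec))) {
    idx <- signal$time >= rec$time[k]
    out$time[idx] <- out$time[idx] + rec$duration[k]
    shift <- shift + rec$duration[k]
  }
  list(signal = out, records = rec)
}

#' Simulate one grasp-and-lift trial
#'
#' Generates a noise-free ("true") trajectory at the configured sensor rates,
#' with ground truth (phase boundaries, attained force, injected delays,
#' outcome label and error events) attached. Pass the result through
#' [sense()] to obtain the measured trajectory (clipped, resampled, noisy).
#'
#' The object lifts off if and only if the grip force attained at lift onset
#' keeps the two-finger friction cone closed against the object's weight; it
#' survives the whole lift only if the cone also holds against the peak
#' inertial load of the minimum-jerk lift profile.
#'
#' @param object An [object_spec()].
#' @param controller A [controller_config()].
#' @param delays A [delay_spec()].
#' @param sensors A [sensor_config()]; fixes the output sampling rates.
#' @param policy A [subject_policy()].
#' @param seed Integer root seed; split internally into independent streams
#'   for delays, perception and mishaps. Identical inputs and seed give
#'   bit-identical output.
#' @return An object of class `grasp_trajectory`.
#' @examples
#' traj <- simulate_trial(object_spec("heavy"), seed = 1)
#' traj
#' @export
simulate_trial <- function(object = object_spec("heavy"),
                           controller = controller_config(),
                           delays = delay_spec(),
                           sensors = sensor_config(),
                           policy = subject_policy(),
                           seed = 1L) {
  if (!inherits(object, "object_spec")) stopf("'object' must be an object_spec")
  if (!inherits(controller, "controller_config")) stopf("'controller' must be a controller_config")
  if (!inherits(delays, "delay_spec")) stopf("'delays' must be a delay_spec")
  if (!inherits(sensors, "sensor_config")) stopf("'sensors' must be a sensor_config")
  if (!inherits(policy, "subject_policy")) stopf("'policy' must be a subject_policy")
  k <- .sim_const
  mu <- object$friction_coefficient
  m <- object$mass
  rate <- controller$ramp_rate
  preload <- controller$contact_preload

  ## --- timing skeleton -----------------------------------------------------
  rec <- draw_delays(delays, derive_seed(seed, "delays"))
  d1 <- if ("pre_movement" %in% rec$insertion_point) {
    rec$duration[rec$insertion_point == "pre_movement"]
  } else 0
  d2 <- if ("pre_ramp" %in% rec$insertion_point) {
    rec$duration[rec$insertion_point == "pre_ramp"]
  } else 0

  close_time <- (k$initial_aperture - object$contact_diameter) / controller$close_speed
  t_contact <- d1 + close_time
  t_ramp_on <- t_contact + d2

  planned <- policy$planned_ramp_duration
  hold <- if (object$name %in% names(planned)) planned[[object$name]] else planned[[1L]]
  target_force <- preload + rate * hold  # force the subject intends to reach

  # flexor release: feedforward timing from perceived contact, optionally
  # blended toward the perceived-force crossing of the target (feedback)
  t_rel_ff <- t_contact + hold
  use_fb <- length(policy$feedback_channels) > 0 && policy$feedback_gain > 0
  if (use_fb) {
    eff_sd <- policy$perceptual_noise_sd / sqrt(length(policy$feedback_channels))
    eps <- with_seed(derive_seed(seed, "perception"), stats::rnorm(1, 0, eff_sd))
    t_rel_fb <- t_ramp_on + max(0, (target_force - preload + eps)) / rate +
      policy$reaction_time
    gain <- min(policy$feedback_gain, 1)
    t_rel <- t_rel_ff + gain * (t_rel_fb - t_rel_ff)
  } else {
    t_rel <- t_rel_ff
  }
  t_rel <- max(t_rel, t_contact)

  engaged <- t_rel > t_contact  # flexor held past contact: preload registers
  f_att <- if (!engaged) 0 else {
    min(preload + rate * max(0, t_rel - t_ramp_on), controller$force_max)
  }
  t_sat <- t_ramp_on + (controller$force_max - preload) / rate
  t_plateau <- if (engaged && t_rel > t_ramp_on) min(t_rel, t_sat) else NA_real_

  t_lift <- t_rel + k$settle
  t_lift_end <- t_lift + k$lift_duration
  t_replace <- t_lift_end + k$hold_duration
  t_replace_end <- t_replace + k$replace_duration
  t_release <- t_replace_end

  ## --- within-trial retry loop ----------------------------------------------
  # A subject whose grip cannot even hold the static weight sees the lift fail
  # (the object stays put), lowers the hand and ramps again with a larger
  # target, up to max_attempts times: trials normally end with the object
  # lifted, at the cost of extra errors and a longer trial.
  a_peak <- min_jerk_peak_acc(k$lift_amplitude, k$lift_duration)
  f_static <- m * GRAVITY / (2 * mu)
  f_dyn <- m * (GRAVITY + a_peak) / (2 * mu)
  max_attempts <- 5L

  rise_end_1 <- if (engaged && t_rel > t_ramp_on) {
    t_ramp_on + (f_att - preload) / rate
  } else NA_real_
  attempts <- list(list(ramp_on = t_ramp_on, rise_end = rise_end_1,
                        f_prev = preload, f = f_att,
                        lift = t_rel + k$settle))
  eff_sd <- policy$perceptual_noise_sd /
    sqrt(max(1L, length(policy$feedback_channels)))
  can_retry <- engaged && hold > 0
  kk <- 1L
  while (can_retry && 2 * mu * attempts[[kk]]$f < m * GRAVITY &&
         attempts[[kk]]$f < controller$force_max && kk < max_attempts) {
    prev <- attempts[[kk]]
    ramp_on <- prev$lift + 2 * k$lift_duration + 0.4  # up, pause, down, pause
    if (use_fb) {
      eps_k <- with_seed(derive_seed(seed, paste0("perception_retry", kk)),
                         stats::rnorm(1, 0, eff_sd))
      f_next <- max(prev$f + 0.5, target_force + 0.75 * kk + eps_k)
    } else {
      f_next <- prev$f + rate * hold  # re-execute the feedforward plan
    }
    f_next <- min(f_next, controller$force_max)
    rise_end <- ramp_on + (f_next - prev$f) / rate
    attempts[[kk + 1L]] <- list(ramp_on = ramp_on, rise_end = rise_end,
                                f_prev = prev$f, f = f_next,
                                lift = rise_end + k$settle)
    kk <- kk + 1L
  }
  K <- kk
  fin <- attempts[[K]]
  f_att <- fin$f
  t_lift <- fin$lift
  t_lift_end <- t_lift + k$lift_duration
  t_replace <- t_lift_end + k$hold_duration
  t_release <- t_replace + k$replace_duration

  ## --- final-attempt outcome -------------------------------------------------
  mishap <- policy$early_release_prob > 0 &&
    with_seed(derive_seed(seed, "mishap"),
              stats::runif(1)) < policy$early_release_prob

  outcome <- "success"
  t_event <- NA_real_
  if (f_att < 1) {
    outcome <- "failed_lift"; t_event <- t_lift
  } else if (2 * mu * f_att < m * GRAVITY) {
    outcome <- "slip"; t_event <- t_lift
  } else if (2 * mu * f_att < m * (GRAVITY + a_peak)) {
    # cone violated mid-lift when the inertial load first exceeds capacity
    a_crit <- (2 * mu * f_att - m * GRAVITY) / m
    tt <- seq(0, k$lift_duration, by = controller$control_dt)
    acc <- min_jerk_acc(tt, k$lift_amplitude, k$lift_duration)
    idx <- which(acc > a_crit)[1L]
    outcome <- "slip"
    t_event <- t_lift + tt[idx]
  } else if (mishap) {
    outcome <- "drop"
    u <- with_seed(derive_seed(seed, "mishap_time"), stats::runif(1))
    t_event <- t_lift_end + 0.1 + u * (k$hold_duration - 0.2)
  }

  t_end <- t_release + f_att / k$release_decay +
    (k$initial_aperture - object$contact_diameter) / controller$open_speed + 0.1
  t_end <- ceiling(t_end / controller$control_dt) * controller$control_dt

  ## --- hand (thumb) vertical profile ---------------------------------------
  z_hand <- function(t) {
    z <- numeric(length(t))
    for (j in seq_len(K - 1L)) {
      lj <- attempts[[j]]$lift
      z <- z + min_jerk_pos(t - lj, k$lift_amplitude, k$lift_duration) -
        min_jerk_pos(t - (lj + k$lift_duration + 0.2),
                     k$lift_amplitude, k$lift_duration)
    }
    z + min_jerk_pos(t - t_lift, k$lift_amplitude, k$lift_duration) -
      min_jerk_pos(t - t_replace, k$lift_amplitude, k$replace_duration)
  }

  ## --- object vertical profile, per outcome --------------------------------
  # the object stays on the table through every failed attempt; it can only
  # move with the final-attempt hand excursion
  z_hand_final <- function(t) {
    min_jerk_pos(t - t_lift, k$lift_amplitude, k$lift_duration) -
      min_jerk_pos(t - t_replace, k$lift_amplitude, k$replace_duration)
  }
  z_object <- function(t) {
    if (outcome == "failed_lift") return(rep(0, length(t)))
    zh <- z_hand_final(t)
    if (outcome == "success") return(zh)
    if (outcome == "slip") {
      if (t_event <= t_lift) return(rep(0, length(t))) # never leaves the table
      zs <- z_hand_final(t_event)
      v0 <- min_jerk_vel(t_event - t_lift, k$lift_amplitude, k$lift_duration)
      td <- v0 / k$slip_decel
      z_final <- zs + v0^2 / (2 * k$slip_decel)
      dt <- t - t_event
      z <- ifelse(t < t_event, zh,
            ifelse(dt < td, zs + v0 * dt - 0.5 * k$slip_decel * dt^2, z_final))
      # the object is still in the (slipped) grasp: it follows the hand down
      z <- ifelse(t >= t_replace, pmin(z_final, zh), z)
      return(pmax(z, 0))
    }
    # drop: free fall from the hold height, then rests on the table
    dt <- pmax(t - t_event, 0)
    ifelse(t < t_event, zh, pmax(k$lift_amplitude - 0.5 * GRAVITY * dt^2, 0))
  }

  ## --- grip-force profile on the force grid --------------------------------
  tf <- seq(0, t_end, by = 1 / sensors$force_rate)
  f <- numeric(length(tf))
  if (engaged) {
    f[tf >= t_contact] <- preload
    for (j in seq_len(K)) {
      at <- attempts[[j]]
      if (!is.na(at$rise_end) && at$rise_end > at$ramp_on) {
        ramp <- tf >= at$ramp_on & tf < at$rise_end
        f[ramp] <- pmin(at$f_prev + rate * (tf[ramp] - at$ramp_on),
                        controller$force_max)
        f[tf >= at$rise_end] <- at$f
      } else {
        f[tf >= at$ramp_on] <- at$f
      }
    }
    if (outcome == "drop") {
      dec <- tf >= t_event + k$drop_grip_hold
      f[dec] <- pmax(f_att - k$release_decay *
                       (tf[dec] - t_event - k$drop_grip_hold), 0)
    } else {
      dec <- tf >= t_release
      f[dec] <- pmax(f_att - k$release_decay * (tf[dec] - t_release), 0)
    }
  }

  ## --- aperture and control signals ----------------------------------------
  aperture_at <- function(t) {
    a <- k$initial_aperture - controller$close_speed * pmax(t - d1, 0)
    a <- pmax(a, object$contact_diameter)
    opening <- t >= t_release
    a[opening] <- pmin(object$contact_diameter +
                         controller$open_speed * (t[opening] - t_release),
                       k$initial_aperture)
    a
  }
  flexor <- as.integer(tf <= t_rel)
  if (K > 1L) {
    for (j in 2:K) {
      at <- attempts[[j]]
      flexor[tf >= at$ramp_on & tf <= at$rise_end] <- 1L
    }
  }
  extensor <- as.integer(tf >= t_release & tf <= t_release +
                           (k$initial_aperture - object$contact_diameter) /
                           controller$open_speed)

  ## --- position channels on the position grid ------------------------------
  tp <- seq(0, t_end, by = 1 / sensors$position_rate)
  zh <- z_hand(tp)
  zo <- z_object(tp)
  ap <- aperture_at(tp)
  base <- object$baseline_height
  mk <- function(x, y, z) data.frame(time = tp, x = x, y = y, z = z)
  positions <- list(
    thumb_tip  = mk(-ap / 2, 0, base + k$thumb_grasp_height + zh),
    forefinger = mk( ap / 2, 0, base + k$thumb_grasp_height + zh),
    wrist      = mk(-0.10,  0, base + 0.05 + zh),
    object_base = mk(0, 0, base + zo)
  )

  ## --- ground truth ---------------------------------------------------------
  tc_fine <- seq(0, t_end, by = controller$control_dt)
  zo_fine <- z_object(tc_fine)
  above <- zo_fine > 0.005
  elev <- if (any(above)) {
    c(start = tc_fine[which(above)[1L]], end = tc_fine[max(which(above))])
  } else c(start = NA_real_, end = NA_real_)

  events <- data.frame(kind = character(), time = numeric(),
                       stringsAsFactors = FALSE)
  for (j in seq_len(K - 1L)) {
    at <- attempts[[j]]
    events <- rbind(events, data.frame(
      kind = if (at$f < 1) "failed_lift" else "slip",
      time = at$lift, stringsAsFactors = FALSE))
  }
  if (outcome != "success") {
    events <- rbind(events, data.frame(kind = outcome, time = t_event,
                                       stringsAsFactors = FALSE))
  }

  ground_truth <- list(
    outcome = outcome,
    events = events,
    n_attempts = K,
    contact_time = t_contact,
    ramp_start = if (engaged) t_contact else NA_real_,
    ramp_end = if (!engaged) NA_real_ else if (K > 1L) fin$rise_end else t_plateau,
    flexor_release = if (K > 1L) fin$rise_end else t_rel,
    lift_onset = t_lift,
    elevation_start = unname(elev["start"]),
    elevation_end = unname(elev["end"]),
    trial_start = 0,
    trial_end = t_end,
    true_peak_force = f_att,
    planned_hold = unname(hold),
    slip_threshold_static = f_static,
    slip_threshold_dynamic = f_dyn
  )

  structure(
    list(
      force = data.frame(time = tf, force = f),
      positions = positions,
      aperture = data.frame(time = tp, aperture = ap),
      control = data.frame(time = tf, flexor = flexor, extensor = extensor),
      injected_delays = rec,
      ground_truth = ground_truth,
      object = object, controller = controller, sensors = sensors,
      seed = seed, measured = FALSE
    ),
    class = "grasp_trajectory"
  )
}

#' Apply the sensing model to a true trajectory
#'
#' Resamples the force channel at `sensors$force_rate`, clipping it to the
#' sensor's linear range `[0, force_linear_max]` (saturation), and resamples
#' all position channels and the aperture at `sensors$position_rate`, adding
#' independent Gaussian measurement noise per channel as configured. With zero
#' noise and forces inside the linear range, sensing is the identity at shared
#' timestamps.
#'
#' @param traj A `grasp_trajectory` (true, from [simulate_trial()]).
#' @param sensors A [sensor_config()]; defaults to the configuration the
#'   trajectory was simulated with.
#' @param seed Integer seed for the measurement noise.
#' @return A `grasp_trajectory` with `measured = TRUE`.
#' @export
sense <- function(traj, sensors = traj$sensors, seed = NULL) {
  stopifnot(inherits(traj, "grasp_trajectory"))
  if (!inherits(sensors, "sensor_config")) stopf("'sensors' must be a sensor_config")
  t0 <- min(traj$force$time)
  t1 <- max(traj$force$time)
  tf <- seq(t0, t1, by = 1 / sensors$force_rate)
  tp <- seq(t0, t1, by = 1 / sensors$position_rate)

  f <- stats::approx(traj$force$time, traj$force$force, xout = tf, rule = 2)$y
  f <- pmin(pmax(f, 0), sensors$force_linear_max)
  noise_seed <- derive_seed(seed, "sensor_noise")
  meas <- with_seed(noise_seed, {
    if (sensors$force_noise_sd > 0) {
      f <- f + stats::rnorm(length(f), 0, sensors$force_noise_sd)
    }
    positions <- lapply(traj$positions, function(p) {
      out <- data.frame(
        time = tp,
        x = stats::approx(p$time, p$x, xout = tp, rule = 2)$y,
        y = stats::approx(p$time, p$y, xout = tp, rule = 2)$y,
        z = stats::approx(p$time, p$z, xout = tp, rule = 2)$y
      )
      if (sensors$position_noise_sd > 0) {
        out$x <- out$x + stats::rnorm(length(tp), 0, sensors$position_noise_sd)
        out$y <- out$y + stats::rnorm(length(tp), 0, sensors$position_noise_sd)
        out$z <- out$z + stats::rnorm(length(tp), 0, sensors$position_noise_sd)
      }
      out
    })
    list(f = f, positions = positions)
  })

  out <- traj
  out$force <- data.frame(time = tf, force = meas$f)
  out$positions <- meas$positions
  out$aperture <- data.frame(
    time = tp,
    aperture = stats::approx(traj$aperture$time, traj$aperture$aperture,
                             xout = tp, rule = 2)$y
  )
  out$control <- data.frame(
    time = tf,
    flexor = stats::approx(traj$control$time, traj$control$flexor, xout = tf,
                           method = "constant", rule = 2)$y,
    extensor = stats::approx(traj$control$time, traj$control$extensor,
                             xout = tf, method = "constant", rule = 2)$y
  )
  out$sensors <- sensors
  out$measured <- TRUE
  out
}

#' Trial-to-trial policy adaptation
#'
#' Updates the subject's planned flexor hold duration for each object from the
#' outcomes of previous trials, emulating trial-and-error learning driven by
#' the end-of-trial peak-force display. Per object, the rule keeps the lowest
#' planned hold that succeeded (no errors) and the highest that failed, then
#' probes downward while every trial succeeds, retreats upward while every
#' trial fails, and bisects between the two once both are known, settling on
#' the lowest known-successful hold when the bracket is tighter than
#' `resolution`.
#'
#' @param policy A [subject_policy()].
#' @param history Data frame of prior trials with columns `object` (name),
#'   `planned` (hold used, s) and `e` (error count). Empty history leaves the
#'   policy unchanged.
#' @param probe_step Downward probe per fully-successful update, s.
#' @param retreat_step Upward step per fully-failed update, s.
#' @param resolution Bracket width below which the plan stops moving, s.
#' @return The updated `subject_policy`.
#' @export
adapt_subject_policy <- function(policy, history,
                                 probe_step = 0.1, retreat_step = 0.2,
                                 resolution = 0.1) {
  stopifnot(inherits(policy, "subject_policy"))
  if (is.null(history) || nrow(history) == 0L) return(policy)
  stopifnot(all(c("object", "planned", "e") %in% names(history)))
  planned <- policy$planned_ramp_duration
  for (obj in unique(history$object)) {
    h <- history[history$object == obj, , drop = FALSE]
    ok <- h$e == 0
    L <- if (any(ok)) min(h$planned[ok]) else NA_real_
    H <- if (any(!ok)) max(h$planned[!ok]) else NA_real_
    cur <- if (obj %in% names(planned)) planned[[obj]] else planned[[1L]]
    new <- cur
    if (!is.na(L) && is.na(H)) {
      new <- max(L - probe_step, 0.02)
    } else if (is.na(L) && !is.na(H)) {
      new <- H + retreat_step
    } else if (!is.na(L) && !is.na(H)) {
      if (H >= L) {
        new <- L + resolution  # inconsistent bracket (e.g. random delays)
      } else if (L - H > resolution) {
        new <- (L + H) / 2
      } else {
        new <- L
      }
    }
    planned[[obj]] <- new
  }
  policy$planned_ramp_duration <- planned
  policy
}

#' @export
print.grasp_trajectory <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<grasp_trajectory%s> %.2f s, object '%s' (%.0f g)\n",
              if (isTRUE(x$measured)) " (measured)" else "",
              max(x$force$time), x$object$name, x$object$mass * 1000))
  cat(sprintf("  outcome: %s; peak grip %.2f N; contact %.3f s; %d injected delay(s)\n",
              gt$outcome, gt$true_peak_force, gt$contact_time,
              nrow(x$injected_delays)))
  invisible(x)
}

#' @export
plot.grasp_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$force$time, x$force$force, type = "l",
                 xlab = "", ylab = "grip force [N]", ...)
  graphics::plot(x$positions$object_base$time, x$positions$object_base$z,
                 type = "l", xlab = "", ylab = "elevation [m]", col = 2)
  graphics::lines(x$positions$thumb_tip$time, x$positions$thumb_tip$z, col = 4)
  graphics::legend("topright", c("object", "thumb"), col = c(2, 4), lty = 1,
                   bty = "n")
  graphics::plot(x$aperture$time, x$aperture$aperture, type = "l",
                 xlab = "time [s]", ylab = "aperture [m]")
  invisible(x)
}
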