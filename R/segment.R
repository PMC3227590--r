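# Automatic trajectory segmentation and rule-based error detection.
#
# The detector implements the study's operational error definitions:
#   drop        - stable grasp (grip > 1 N, fingers closed on the object) and
#                 the object's downward acceleration exceeds the thumb's by
#                 more than 5 m/s^2;
#   slip        - stable grasp and the thumb's upward velocity exceeds the
#                 object's by more than 0.05 m/s;
#   failed lift - grip below 1 N and the same 0.05 m/s velocity criterion.
# Events closer together than 60 ms are counted once.
#
# Positions are smoothed with a 20 ms moving average before central-difference
# differentiation; 240 Hz tracking needs smoothing before velocities and
# accelerations are stable enough to threshold.

# centred moving average with edge replication
#' @noRd
smooth_ma <- function(x, width_s, rate) {
  w <- max(1L, round(width_s * rate))
  if (w %% 2L == 0L) w <- w + 1L
  if (w <= 1L || length(x) < w) return(x)
  half <- (w - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2L))[(half + 1L):(half + length(x))]
}

# central differences (one-sided at the ends)
#' @noRd
central_diff <- function(x, t) {
  n <- length(x)
  if (n < 3L) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1L] <- (x[2L] - x[1L]) / (t[2L] - t[1L])
  d[n] <- (x[n] - x[n - 1L]) / (t[n] - t[n - 1L])
  d
}

#' @noRd
require_channel <- function(traj, channel) {
  ok <- switch(channel,
    force = is.data.frame(traj$force) && nrow(traj$force) > 0,
    aperture = is.data.frame(traj$aperture) && nrow(traj$aperture) > 0,
    !is.null(traj$positions[[channel]]) && nrow(traj$positions[[channel]]) > 0
  )
  if (!isTRUE(ok)) stopf("required channel '%s' is missing from the trajectory", channel)
  invisible(TRUE)
}

# first time a logical vector is TRUE for at least `sustain` seconds
#' @noRd
first_sustained <- function(cond, t, sustain) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- if (length(t) > 1L) t[2L] - t[1L] else 0
  need <- max(1L, ceiling(sustain / max(dt, .Machine$double.eps)))
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit)) return(NA_real_)
  t[starts[hit[1L]]]
}

#' Segment a grasp-and-lift trajectory into phases
#'
#' Locates the start and end of the force ramp and the period(s) for which the
#' object was elevated, plus the moment of contact, and labels every force
#' sample with its phase. Boundaries that cannot be located are flagged absent
#' (`NA`), never silently defaulted.
#'
#' The ramp starts at the first sustained crossing of the contact-force
#' threshold (the contact preload registers immediately on contact, so this
#' lands on the moment of contact even when a random pre-ramp delay holds the
#' ramp off) and ends when the force first reaches its plateau.
#'
#' @param traj A `grasp_trajectory` (true or measured), or any object with the
#'   same `force` / `positions` / `aperture` channels.
#' @param contact_force_threshold Force threshold marking contact, N.
#' @param sustain Time the threshold must be held to count as a crossing, s.
#' @param elevation_threshold Object-base height above baseline that counts as
#'   elevated, m.
#' @param plateau_tol Force distance from the within-trial maximum at which the
#'   ramp is considered to have plateaued, N.
#' @param aperture_tol Aperture slack above the object's contact diameter used
#'   to locate the moment of contact, m.
#' @return An object of class `segmented_trial`.
#' @export
segment_trial <- function(traj,
                          contact_force_threshold = 0.2,
                          sustain = 0.02,
                          elevation_threshold = 0.005,
                          plateau_tol = 0.01,
                          aperture_tol = 5e-4) {
  require_channel(traj, "force")
  require_channel(traj, "object_base")
  tf <- traj$force$time
  f <- traj$force$force
  trial_start <- min(tf)
  trial_end <- max(tf)

  ramp_start <- first_sustained(f > contact_force_threshold, tf, sustain)
  ramp_end <- NA_real_
  if (!is.na(ramp_start)) {
    in_grasp <- tf >= ramp_start
    fmax <- max(f[in_grasp])
    idx <- which(in_grasp & f >= fmax - plateau_tol)[1L]
    ramp_end <- tf[idx]
  }

  # contact: aperture reaching the object's contact diameter, if available;
  # otherwise the force-threshold crossing stands in
  contact_time <- ramp_start
  if (is.data.frame(traj$aperture) && nrow(traj$aperture) > 0 &&
      !is.null(traj$object$contact_diameter)) {
    ta <- traj$aperture$time
    hit <- which(traj$aperture$aperture <= traj$object$contact_diameter + aperture_tol)
    if (length(hit)) contact_time <- ta[hit[1L]]
  }

  # elevation: object base above its resting baseline
  po <- traj$positions$object_base
  baseline <- traj$object$baseline_height %||%
    stats::median(po$z[po$time <= min(po$time) + 0.1])
  up <- po$z > baseline + elevation_threshold
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  intervals <- if (length(keep)) {
    data.frame(start = po$time[starts[keep]], end = po$time[ends[keep]])
  } else data.frame(start = numeric(), end = numeric())

  elevation_start <- if (nrow(intervals)) intervals$start[1L] else NA_real_
  elevation_end <- if (nrow(intervals)) intervals$end[nrow(intervals)] else NA_real_

  # per-sample phase labels on the force timebase
  phase <- rep("reach", length(tf))
  if (!is.na(contact_time)) phase[tf >= contact_time] <- "contact"
  if (!is.na(ramp_start)) phase[tf >= ramp_start] <- "ramp"
  if (!is.na(ramp_end)) phase[tf >= ramp_end] <- "hold"
  for (i in seq_len(nrow(intervals))) {
    phase[tf >= intervals$start[i] & tf <= intervals$end[i]] <- "elevated"
  }
  if (!is.na(elevation_end)) phase[tf > elevation_end] <- "release"

  structure(
    list(trial_start = trial_start, trial_end = trial_end,
         contact_time = contact_time,
         ramp_start = ramp_start, ramp_end = ramp_end,
         elevation_start = elevation_start, elevation_end = elevation_end,
         elevation_intervals = intervals,
         phase_labels = data.frame(time = tf, phase = phase),
         flags = list(ramp_absent = is.na(ramp_start),
                      elevation_absent = nrow(intervals) == 0L,
                      contact_absent = is.na(contact_time))),
    class = "segmented_trial"
  )
}

#' @export
print.segmented_trial <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.3f s", v)
  cat("<segmented_trial>\n")
  cat(sprintf("  contact %s; ramp %s -> %s; elevation %s -> %s (%d interval(s))\n",
              fmt(x$contact_time), fmt(x$ramp_start), fmt(x$ramp_end),
              fmt(x$elevation_start), fmt(x$elevation_end),
              nrow(x$elevation_intervals)))
  invisible(x)
}

#' Per-sample stable-grasp mask
#'
#' The study's operational definition of a stable grasp: the object is held
#' between thumb and forefinger with grip force above 1 N. Force alone cannot
#' verify finger opposition, so the mask additionally requires the grasp
#' aperture to be at the object's contact diameter (within `aperture_tol`)
#' when an aperture channel and object metadata are available.
#'
#' @param traj A `grasp_trajectory`.
#' @param times Times at which to evaluate the mask; defaults to the force
#'   channel's timestamps.
#' @param force_threshold Stable-grasp force threshold, N.
#' @param aperture_tol Aperture slack above the contact diameter, m.
#' @return Logical vector along `times`.
#' @export
stable_grasp_mask <- function(traj, times = NULL, force_threshold = 1,
                              aperture_tol = 0.005) {
  require_channel(traj, "force")
  if (is.null(times)) times <- traj$force$time
  f <- stats::approx(traj$force$time, traj$force$force, xout = times, rule = 2)$y
  mask <- f > force_threshold
  if (is.data.frame(traj$aperture) && nrow(traj$aperture) > 0 &&
      !is.null(traj$object$contact_diameter)) {
    a <- stats::approx(traj$aperture$time, traj$aperture$aperture,
                       xout = times, rule = 2)$y
    mask <- mask & (a <= traj$object$contact_diameter + aperture_tol)
  }
  mask
}

#' Detect drop, slip and failed-lift events
#'
#' Applies the rule-based error definitions to the thumb and object-base
#' kinematics (smoothed, centrally differentiated) and the grip force. Each
#' contiguous stretch of samples satisfying a rule yields one event at its
#' onset; onsets closer together than `dedup_window` are then merged by
#' [deduplicate_events()].
#'
#' @param traj A `grasp_trajectory`.
#' @param seg Optional [segment_trial()] result (accepted for interface
#'   symmetry; the rules themselves are segmentation-free).
#' @param slip_velocity_threshold Relative upward-velocity threshold, m/s.
#' @param drop_accel_threshold Relative downward-acceleration threshold, m/s^2.
#' @param force_threshold Stable-grasp force threshold, N.
#' @param dedup_window De-duplication window, s.
#' @param smooth_window Moving-average width applied to positions before
#'   differentiation, s.
#' @return Data frame of class `error_events` with columns `kind`, `time`,
#'   `grip_force`, `velocity_diff`, `accel_diff`.
#' @export
detect_errors <- function(traj, seg = NULL,
                          slip_velocity_threshold = 0.05,
                          drop_accel_threshold = 5,
                          force_threshold = 1,
                          dedup_window = 0.06,
                          smooth_window = 0.02) {
  require_channel(traj, "thumb_tip")
  require_channel(traj, "object_base")
  require_channel(traj, "force")
  pt <- traj$positions$thumb_tip
  po <- traj$positions$object_base
  t <- pt$time
  zo <- stats::approx(po$time, po$z, xout = t, rule = 2)$y
  rate <- 1 / stats::median(diff(t))

  zt_s <- smooth_ma(pt$z, smooth_window, rate)
  zo_s <- smooth_ma(zo, smooth_window, rate)
  v_thumb <- central_diff(zt_s, t)
  v_obj <- central_diff(zo_s, t)
  a_thumb <- central_diff(v_thumb, t)
  a_obj <- central_diff(v_obj, t)

  vdiff <- v_thumb - v_obj              # relative upward velocity
  adiff <- a_thumb - a_obj              # object's excess downward acceleration
  f <- stats::approx(traj$force$time, traj$force$force, xout = t, rule = 2)$y
  stable <- stable_grasp_mask(traj, times = t, force_threshold = force_threshold)

  conds <- list(
    drop = stable & adiff > drop_accel_threshold,
    slip = stable & vdiff > slip_velocity_threshold,
    failed_lift = (f < force_threshold) & vdiff > slip_velocity_threshold
  )
  onsets <- lapply(names(conds), function(kind) {
    cond <- conds[[kind]]
    on <- which(cond & !c(FALSE, cond[-length(cond)]))
    if (!length(on)) return(NULL)
    data.frame(kind = kind, time = t[on], grip_force = f[on],
               velocity_diff = vdiff[on], accel_diff = adiff[on],
               stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, onsets)
  if (is.null(events)) {
    events <- data.frame(kind = character(), time = numeric(),
                         grip_force = numeric(), velocity_diff = numeric(),
                         accel_diff = numeric(), stringsAsFactors = FALSE)
  }
  # sort by time; at equal times the more specific (acceleration) rule wins
  kind_rank <- c(drop = 1L, slip = 2L, failed_lift = 3L)
  events <- events[order(events$time, kind_rank[events$kind]), , drop = FALSE]
  rownames(events) <- NULL
  deduplicate_events(events, window = dedup_window)
}

#' Merge error events detected within a common window
#'
#' Greedy left-to-right merge: an event within `window` seconds of the
#' previously kept event is absorbed into it (the earliest event of a merge
#' group, and its kind, are kept). The output count never exceeds the input
#' count and the operation is idempotent.
#'
#' @param events Data frame with at least `kind` and `time`, sorted by time.
#' @param window Merge window, s (study: 0.06).
#' @return The de-duplicated events, class `error_events`.
#' @export
deduplicate_events <- function(events, window = 0.06) {
  stopifnot(is.data.frame(events), all(c("kind", "time") %in% names(events)))
  assert_scalar_num(window, "window", 0)
  if (nrow(events) > 1L && is.unsorted(events$time)) {
    stopf("events must be sorted by time")
  }
  keep <- logical(nrow(events))
  last_kept <- -Inf
  for (i in seq_len(nrow(events))) {
    if (events$time[i] - last_kept > window) {
      keep[i] <- TRUE
      last_kept <- events$time[i]
    }
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("error_events", "data.frame")
  out
}
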