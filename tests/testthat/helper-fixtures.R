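# Shared fixtures: hand-constructed trajectories and randomized simulator
# scenarios, all generated in code at test time.

# A minimal trajectory with analytic channels, for exercising the detector and
# segmentation rules in isolation from the simulator.
make_synthetic_traj <- function(duration = 2, position_rate = 240,
                                force_rate = 1000,
                                thumb_z = function(t) rep(0, length(t)),
                                object_z = function(t) rep(0, length(t)),
                                force = function(t) rep(0, length(t)),
                                aperture = function(t) rep(0.055, length(t)),
                                object = object_spec("heavy"),
                                t0 = 0) {
  tp <- seq(t0, t0 + duration, by = 1 / position_rate)
  tf <- seq(t0, t0 + duration, by = 1 / force_rate)
  mk <- function(z) data.frame(time = tp, x = 0, y = 0, z = z)
  rel <- function(t) t - t0
  structure(list(
    force = data.frame(time = tf, force = force(rel(tf))),
    positions = list(thumb_tip = mk(thumb_z(rel(tp))),
                     forefinger = mk(thumb_z(rel(tp))),
                     wrist = mk(thumb_z(rel(tp))),
                     object_base = mk(object_z(rel(tp)))),
    aperture = data.frame(time = tp, aperture = aperture(rel(tp))),
    control = data.frame(time = tf, flexor = 0L, extensor = 0L),
    injected_delays = data.frame(insertion_point = character(),
                                 duration = numeric()),
    ground_truth = NULL, object = object, controller = controller_config(),
    sensors = sensor_config(), seed = NULL, measured = FALSE),
    class = "grasp_trajectory")
}

# Piecewise-constant-velocity vertical profile: the thumb moves at `v` during
# [on, off], static otherwise.
velocity_pulse_z <- function(v, on, off) {
  function(t) v * (pmin(pmax(t, on), off) - on)
}

# Draw one randomized grasp scenario covering all outcome regimes (forces kept
# clear of the friction-cone boundaries so the realized episode kinematics are
# frank, not marginal).
random_scenario <- function(i) {
  set.seed(20000 + i)
  obj <- object_spec(sample(c("heavy", "light"), 1L))
  mu2 <- 2 * obj$friction_coefficient
  f_static <- obj$mass * 9.81 / mu2
  f_dyn <- obj$mass * (9.81 + 0.1 / 1^2 * 10 / sqrt(3)) / mu2
  regime <- sample(c("fail", "immediate_slip", "mid_slip", "success", "drop"), 1L)
  f_target <- switch(regime,
    fail = runif(1, 0.4, 0.85),
    immediate_slip = runif(1, 1.1, f_static - 0.15),
    mid_slip = runif(1, f_static + 0.02, f_dyn - 0.02),
    success = runif(1, f_dyn + 0.3, 9),
    drop = runif(1, f_dyn + 0.3, 9))
  hold <- (f_target - 0.3) / 5
  policy <- subject_policy(
    planned_ramp_duration = c(heavy = hold, light = hold),
    early_release_prob = as.numeric(regime == "drop"))
  list(object = obj, policy = policy, regime = regime, seed = 30000 + i)
}
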