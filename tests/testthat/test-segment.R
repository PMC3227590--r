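# Automatic segmentation and the rule-based drop/slip/failed-lift detector.

test_that("segmentation boundaries land within 10 ms of simulator ground truth", {
  for (s in 1:5) {
    pol <- subject_policy(c(heavy = 0.8 + 0.15 * s, light = 0.6))
    tr <- simulate_trial(object_spec("heavy"), policy = pol, seed = s)
    seg <- segment_trial(tr)
    gt <- tr$ground_truth
    expect_lt(abs(seg$contact_time - gt$contact_time), 0.010)
    expect_lt(abs(seg$ramp_start - gt$ramp_start), 0.010)
    expect_lt(abs(seg$ramp_end - gt$ramp_end), 0.010)
    if (!is.na(gt$elevation_start)) {
      expect_lt(abs(seg$elevation_start - gt$elevation_start), 0.010)
      expect_lt(abs(seg$elevation_end - gt$elevation_end), 0.010)
    }
  }
})

test_that("an all-zero force stream segments with the ramp flagged absent", {
  tr <- make_synthetic_traj()
  seg <- segment_trial(tr)
  expect_true(seg$flags$ramp_absent)
  expect_true(is.na(seg$ramp_start))
  expect_identical(nrow(seg$elevation_intervals), 0L)
})

test_that("missing channels are rejected by name", {
  tr <- make_synthetic_traj()
  tr$positions$object_base <- NULL
  expect_error(segment_trial(tr), "object_base")
  tr2 <- make_synthetic_traj()
  tr2$force <- NULL
  expect_error(segment_trial(tr2), "force")
  tr3 <- make_synthetic_traj()
  tr3$positions$thumb_tip <- NULL
  expect_error(detect_errors(tr3), "thumb_tip")
})

test_that("boundaries are invariant to uniform time translation", {
  pol <- subject_policy(c(heavy = 1.0, light = 0.6))
  tr <- simulate_trial(object_spec("heavy"), policy = pol, seed = 8)
  shift <- 5.3
  tr2 <- tr
  tr2$force$time <- tr2$force$time + shift
  tr2$aperture$time <- tr2$aperture$time + shift
  tr2$control$time <- tr2$control$time + shift
  tr2$positions <- lapply(tr2$positions, function(p) {
    p$time <- p$time + shift
    p
  })
  s1 <- segment_trial(tr)
  s2 <- segment_trial(tr2)
  for (b in c("contact_time", "ramp_start", "ramp_end",
              "elevation_start", "elevation_end")) {
    expect_equal(s2[[b]] - s1[[b]], shift, tolerance = 1e-9)
  }
})

test_that("a successful trial passes through the canonical phase sequence", {
  tr <- simulate_trial(object_spec("heavy"),
                       policy = subject_policy(c(heavy = 1.0, light = 0.6)),
                       seed = 1)
  seg <- segment_trial(tr)
  expect_true(seg$trial_start <= seg$contact_time)
  expect_true(seg$contact_time <= seg$ramp_start + 0.01)
  expect_true(seg$ramp_start <= seg$ramp_end)
  expect_true(seg$ramp_end <= seg$elevation_start)
  expect_true(seg$elevation_end <= seg$trial_end)
  ph <- unique(seg$phase_labels$phase)
  expect_identical(ph, c("reach", "contact", "ramp", "hold", "elevated", "release"))
})

test_that("stable-grasp mask follows the 1 N threshold and the aperture", {
  low <- make_synthetic_traj(force = function(t) rep(0.5, length(t)))
  expect_false(any(stable_grasp_mask(low)))
  high <- make_synthetic_traj(force = function(t) rep(3, length(t)))
  expect_true(all(stable_grasp_mask(high)))
  open <- make_synthetic_traj(force = function(t) rep(3, length(t)),
                              aperture = function(t) rep(0.10, length(t)))
  expect_false(any(stable_grasp_mask(open)))
})

test_that("the mask flips within one sample of a force threshold crossing", {
  t_star <- 1.0
  tr <- make_synthetic_traj(force = function(t) 0.5 + 1 * (t >= t_star))
  m <- stable_grasp_mask(tr)
  flip <- tr$force$time[which(m)[1L]]
  expect_lt(abs(flip - t_star), 1 / 1000 + 1e-9)
  expect_true(all(m[tr$force$time >= flip]))
})

test_that("a simulated drop is detected as exactly one drop near its true time", {
  pol <- subject_policy(c(heavy = 1.2, light = 0.7), early_release_prob = 1)
  tr <- simulate_trial(object_spec("heavy"), policy = pol, seed = 11)
  expect_identical(tr$ground_truth$outcome, "drop")
  ev <- detect_errors(tr)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "drop")
  expect_lt(abs(ev$time - tr$ground_truth$events$time), 0.05)
})

test_that("a motionless zero-force stream produces no events", {
  tr <- make_synthetic_traj()
  expect_identical(nrow(detect_errors(tr)), 0L)
})

test_that("a weakly gripped rising thumb over a stationary object is a failed lift", {
  tr <- make_synthetic_traj(duration = 3,
                            thumb_z = velocity_pulse_z(0.1, 1, 2),
                            force = function(t) rep(0.2, length(t)))
  ev <- detect_errors(tr)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "failed_lift")
})

test_that("slip detection is sharp at the 0.05 m/s velocity threshold", {
  for (v in c(0.049, 0.051)) {
    tr <- make_synthetic_traj(duration = 3,
                              thumb_z = velocity_pulse_z(v, 1, 2),
                              force = function(t) rep(2, length(t)))
    ev <- detect_errors(tr)
    if (v > 0.05) {
      expect_identical(ev$kind, "slip")
    } else {
      expect_identical(nrow(ev), 0L)
    }
  }
})

test_that("event deduplication merges within the 60 ms window, greedily", {
  ev <- function(kind, time) data.frame(kind = kind, time = time,
                                        stringsAsFactors = FALSE)
  expect_identical(nrow(deduplicate_events(ev("slip", c(1.000, 1.040)))), 1L)
  expect_identical(nrow(deduplicate_events(ev("slip", c(1.000, 1.100)))), 2L)
  expect_identical(nrow(deduplicate_events(ev(character(), numeric()))), 0L)
  # earliest event of a mixed-kind group is kept
  mixed <- deduplicate_events(ev(c("drop", "slip"), c(1.000, 1.030)))
  expect_identical(mixed$kind, "drop")
  # chained events collapse onto the first of each greedy group
  chain <- deduplicate_events(ev("slip", c(1.00, 1.05, 1.10, 1.20)))
  expect_equal(chain$time, c(1.00, 1.10, 1.20))
  expect_error(deduplicate_events(ev("slip", c(2, 1))), "sorted")
})

test_that("deduplication is idempotent and never increases the count", {
  set.seed(1)
  for (i in 1:20) {
    times <- sort(runif(sample(1:15, 1), 0, 2))
    ev <- data.frame(kind = sample(c("drop", "slip", "failed_lift"),
                                   length(times), replace = TRUE),
                     time = times, stringsAsFactors = FALSE)
    once <- deduplicate_events(ev)
    expect_lte(nrow(once), nrow(ev))
    expect_identical(deduplicate_events(once), once)
  }
})
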