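# Gated-ramp controller simulation: configuration contracts, ramp kinetics,
# delay injection, friction-cone checks, sensing and trial-to-trial learning.

test_that("invalid configurations are rejected with the violated invariant named", {
  expect_error(object_spec("x", mass = -1), "mass")
  expect_error(controller_config(ramp_rate = 0), "ramp_rate")
  expect_error(delay_spec(TRUE, low = 1, high = 0.5), "low <= high")
  expect_error(sensor_config(force_rate = -1), "force_rate")
  expect_error(subject_policy(c(heavy = -0.1)), "planned_ramp_duration")
  expect_error(subject_policy(0.5), "named")
})

test_that("identical configs and seed give bit-identical trajectories", {
  args <- list(object = object_spec("heavy"), delays = delay_spec(TRUE),
               policy = subject_policy(c(heavy = 1, light = 0.6),
                                       feedback_gain = 1,
                                       feedback_channels = "visual"),
               seed = 42L)
  expect_identical(do.call(simulate_trial, args), do.call(simulate_trial, args))
})

test_that("grip force ramps linearly at the configured rate after contact", {
  tr <- simulate_trial(object_spec("heavy"),
                       policy = subject_policy(c(heavy = 1.0, light = 0.6)),
                       seed = 1)
  gt <- tr$ground_truth
  sel <- tr$force$time >= gt$ramp_start & tr$force$time <= gt$ramp_end
  fit <- stats::lm(force ~ time, data = tr$force[sel, ])
  expect_equal(unname(stats::coef(fit)[2L]), 5, tolerance = 1e-9)
  expect_lt(max(abs(stats::resid(fit))), 1e-6)
})

test_that("a 1 s flexor hold yields a final grip force of about 5 N", {
  tr <- simulate_trial(object_spec("heavy"),
                       policy = subject_policy(c(heavy = 1.0, light = 0.6)),
                       seed = 1)
  expect_lt(abs(tr$ground_truth$true_peak_force - 5), 0.35)
})

test_that("the commanded force saturates exactly at force_max", {
  tr <- simulate_trial(object_spec("heavy"),
                       policy = subject_policy(c(heavy = 10, light = 10)),
                       seed = 2)
  expect_identical(max(tr$force$force), 15)
  expect_true(all(tr$force$force <= 15))
})

test_that("no commanded ramp means zero grip force and a failed lift", {
  tr <- simulate_trial(object_spec("heavy"),
                       policy = subject_policy(c(heavy = 0, light = 0)),
                       seed = 3)
  expect_true(all(tr$force$force == 0))
  expect_identical(tr$ground_truth$outcome, "failed_lift")
})

test_that("true grip force never exceeds force_max across random scenarios", {
  for (i in 1:20) {
    sc <- random_scenario(i)
    tr <- simulate_trial(sc$object, policy = sc$policy, seed = sc$seed)
    expect_true(all(tr$force$force <= tr$controller$force_max + 1e-12))
    expect_true(all(tr$force$force >= 0))
  }
})

test_that("inject_delays: identity when disabled, exact degenerate draws", {
  sig <- data.frame(time = seq(0, 1, by = 0.01), v = 0)
  off <- inject_delays(sig, delay_spec(enabled = FALSE), seed = 1)
  expect_identical(off$signal, sig)
  expect_identical(nrow(off$records), 0L)

  deg <- inject_delays(sig, delay_spec(TRUE, low = 0.4, high = 0.4), seed = 1,
                       insertion_times = c(pre_movement = 0, pre_ramp = 0.5))
  expect_equal(deg$records$duration, c(0.4, 0.4))
})

test_that("injected delays are uniform with the configured mean", {
  d <- vapply(1:5000, function(s) {
    draws <- inject_delays(data.frame(time = 0:1),
                           delay_spec(TRUE, 0, 1.5), seed = s,
                           insertion_times = c(pre_movement = 0, pre_ramp = 1))
    draws$records$duration
  }, numeric(2))
  se <- (1.5 / sqrt(12)) / sqrt(length(d))
  expect_lt(abs(mean(d) - 0.75), 3 * se)
})

test_that("delay records equal the time shift they induce in the stream", {
  sig <- data.frame(time = seq(0, 2, by = 0.05))
  res <- inject_delays(sig, delay_spec(TRUE, 0, 1.5), seed = 9,
                       insertion_times = c(pre_movement = 0, pre_ramp = 1))
  shift <- res$signal$time[nrow(sig)] - sig$time[nrow(sig)]
  expect_equal(shift, sum(res$records$duration))
})

test_that("slip_check implements the closed two-finger friction cone", {
  expect_identical(slip_check(0, 1.47, 0.4), "slipping")
  expect_identical(slip_check(15, 2.94, 0.4), "stable")
  load <- 2.5
  expect_identical(slip_check(load / (2 * 0.4), load, 0.4), "stable")
  expect_identical(slip_check(load / (2 * 0.4) - 1e-9, load, 0.4), "slipping")
  expect_error(slip_check(-1, 1, 0.4), "negative")
})

test_that("a simulated trial is a slip/drop iff the cone opens during elevation", {
  # mid-lift slip: the cone holds statically but not at peak inertial load
  sc_slip <- simulate_trial(object_spec("heavy"),
                            policy = subject_policy(c(heavy = 0.70, light = 0.7)),
                            seed = 5)
  expect_identical(sc_slip$ground_truth$outcome, "slip")
  f <- sc_slip$ground_truth$true_peak_force
  a_pk <- 0.1 * 10 / sqrt(3)
  loads <- 0.3 * (9.81 + seq(0, a_pk, length.out = 50))
  expect_true(any(slip_check(f, loads, 0.4) == "slipping"))

  sc_ok <- simulate_trial(object_spec("heavy"),
                          policy = subject_policy(c(heavy = 1.2, light = 0.7)),
                          seed = 5)
  expect_identical(sc_ok$ground_truth$outcome, "success")
  f2 <- sc_ok$ground_truth$true_peak_force
  expect_true(all(slip_check(f2, loads, 0.4) == "stable"))
})

test_that("sensing clips at the linear range and is the identity otherwise", {
  tr <- make_synthetic_traj(force = function(t) rep(12, length(t)))
  ms <- sense(tr)
  expect_true(all(ms$force$force == 10))

  tr2 <- simulate_trial(object_spec("heavy"),
                        policy = subject_policy(c(heavy = 1, light = 0.6)),
                        seed = 4)
  ms2 <- sense(tr2)
  expect_equal(ms2$force$force, tr2$force$force)
  expect_equal(ms2$positions$thumb_tip$z, tr2$positions$thumb_tip$z)
})

test_that("sensor noise has the configured scale and is seed-reproducible", {
  tr <- make_synthetic_traj(duration = 10, force = function(t) rep(5, length(t)))
  sn <- sensor_config(force_noise_sd = 0.1)
  ms <- sense(tr, sn, seed = 7)
  resid <- ms$force$force - 5
  expect_lt(abs(stats::sd(resid) - 0.1) / 0.1, 0.1)
  expect_identical(sense(tr, sn, seed = 7), ms)
})

test_that("policy adaptation: no history means no change; over-grip shrinks the plan", {
  pol <- subject_policy(c(heavy = 1.2, light = 0.8))
  expect_identical(adapt_subject_policy(pol, NULL), pol)
  expect_identical(adapt_subject_policy(pol, data.frame()), pol)

  h <- data.frame(object = "heavy", planned = 1.2, e = 0L)
  pol2 <- adapt_subject_policy(pol, h)
  expect_lt(pol2$planned_ramp_duration[["heavy"]],
            pol$planned_ramp_duration[["heavy"]])
  expect_identical(pol2$planned_ramp_duration[["light"]],
                   pol$planned_ramp_duration[["light"]])
})

test_that("repeated trials converge within 0.5 N of the minimal stable force", {
  pol <- subject_policy(c(heavy = 1.6, light = 1.0))
  hist <- data.frame(object = character(), planned = numeric(), e = integer())
  f_dyn <- NA_real_
  for (i in 1:15) {
    planned <- pol$planned_ramp_duration[["heavy"]]
    tr <- simulate_trial(object_spec("heavy"), policy = pol, seed = 500 + i)
    f_dyn <- tr$ground_truth$slip_threshold_dynamic
    hist <- rbind(hist, data.frame(object = "heavy", planned = planned,
                                   e = nrow(tr$ground_truth$events)))
    pol <- adapt_subject_policy(pol, hist)
  }
  f_final <- 0.3 + 5 * pol$planned_ramp_duration[["heavy"]]
  expect_gte(f_final, f_dyn)
  expect_lt(f_final - f_dyn, 0.5)
})

test_that("failed attempts trigger within-trial retries that end in a lift", {
  tr <- simulate_trial(object_spec("heavy"), delays = delay_spec(TRUE),
                       policy = subject_policy(c(heavy = 0.9, light = 0.7)),
                       seed = 13)
  gt <- tr$ground_truth
  expect_gt(gt$n_attempts, 1L)
  expect_identical(gt$outcome, "success")
  expect_identical(nrow(gt$events), gt$n_attempts - 1L)
  expect_false(is.na(gt$elevation_start))
})
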