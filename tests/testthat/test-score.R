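# Per-trial measures and the compound grasp score with per-subject norms.

no_events <- data.frame(kind = character(), time = numeric(),
                        stringsAsFactors = FALSE)

test_that("f is the mean grip force over the elevation interval", {
  tr <- make_synthetic_traj(duration = 2.5,
                            object_z = function(t) 0.05 * (t >= 0.5 & t <= 1.5),
                            force = function(t) rep(3, length(t)))
  seg <- segment_trial(tr)
  m <- trial_metrics(tr, seg, no_events)
  expect_equal(m$f, 3)
  expect_true(m$f_defined)
})

test_that("r excludes the injected pre-ramp delay", {
  pol <- subject_policy(c(heavy = 0.8, light = 0.8), feedback_gain = 1,
                        perceptual_noise_sd = 0, reaction_time = 0,
                        feedback_channels = "visual")
  dl <- delay_spec(TRUE, low = 0.5, high = 0.5, insertion_points = "pre_ramp")
  tr <- simulate_trial(object_spec("light"), delays = dl, policy = pol, seed = 2)
  seg <- segment_trial(tr)
  raw_span <- (seg$ramp_end - seg$ramp_start) * 1000
  m <- trial_metrics(tr, seg, no_events)
  expect_equal(raw_span, 1300, tolerance = 0.01)
  expect_equal(m$r, 800, tolerance = 0.01)
})

test_that("a 0.6 s flexor hold gives f at the closed-form ramp endpoint", {
  pol <- subject_policy(c(heavy = 0.6, light = 0.6))
  tr <- simulate_trial(object_spec("light"), policy = pol, seed = 3)
  seg <- segment_trial(tr)
  m <- trial_metrics(tr, seg, no_events)
  endpoint <- 0.3 + 5 * 0.6  # contact preload + ramp_rate * hold
  expect_lt(abs(m$f - endpoint), 0.2)
})

test_that("f is flagged undefined, not zero, when the object was never elevated", {
  tr <- make_synthetic_traj(force = function(t) rep(3, length(t)))
  seg <- segment_trial(tr)
  m <- trial_metrics(tr, seg, no_events)
  expect_true(is.na(m$f))
  expect_false(m$f_defined)
})

test_that("target/peak follow the error-free minimum and overall maximum", {
  trials <- data.frame(subject_id = 1, f = c(2, 3, 5), r = c(10, 20, 30),
                       d = c(100, 200, 300), e = c(0L, 0L, 0L))
  n <- subject_norms(trials)
  expect_equal(unname(n$target["f"]), 2)
  expect_equal(unname(n$peak["f"]), 5)

  trials2 <- data.frame(subject_id = 1, f = c(2, 3), r = c(1, 2), d = c(1, 2),
                        e = c(1L, 0L))
  n2 <- subject_norms(trials2)
  expect_equal(unname(n2$target["f"]), 3)  # error trial excluded from target
  expect_equal(unname(n2$peak["f"]), 3)

  single <- data.frame(subject_id = 1, f = 4, r = 5, d = 6, e = 0L)
  n3 <- subject_norms(single)
  expect_equal(unname(n3$target["f"]), unname(n3$peak["f"]))
})

test_that("with no error-free trials the target falls back with a flag", {
  trials <- data.frame(subject_id = 1, f = c(2, 3), r = c(1, 2), d = c(1, 2),
                       e = c(1L, 2L))
  n <- subject_norms(trials)
  expect_true(n$no_error_free)
  expect_equal(unname(n$target["f"]), 2)
})

test_that("normalisation maps target to 0, peak to 1, linearly between", {
  n <- subject_norms(data.frame(subject_id = 1, f = c(2, 3, 5), r = c(1, 2, 3),
                                d = c(1, 2, 3), e = c(0L, 0L, 0L)))
  expect_equal(normalize_measure(2, n, "f"), 0)
  expect_equal(normalize_measure(5, n, "f"), 1)
  expect_equal(normalize_measure(3.5, n, "f"), 0.5)
  # below-target values give negative norms, retained not clipped
  expect_lt(normalize_measure(1.5, n, "f"), 0)
})

test_that("peak == target degenerates to norm 0", {
  n <- subject_norms(data.frame(subject_id = 1, f = c(4, 4), r = c(4, 4),
                                d = c(4, 4), e = c(0L, 0L)))
  expect_equal(normalize_measure(4, n, "f"), 0)
})

test_that("the grasp score is the exact sum of the three norms and the errors", {
  trials <- data.frame(subject_id = 1, f = c(2, 3, 5), r = c(10, 20, 40),
                       d = c(100, 150, 300), e = c(0L, 0L, 0L))
  n <- subject_norms(trials)
  best <- grasp_score(list(f = 2, r = 10, d = 100, e = 0L), n)
  expect_identical(best$s, 0)
  worst <- grasp_score(list(f = 5, r = 40, d = 300, e = 0L), n)
  expect_identical(worst$s, 3)
  err2 <- grasp_score(list(f = 2, r = 10, d = 100, e = 2L), n)
  expect_identical(err2$s, 2)
  undef <- grasp_score(list(f = NA_real_, r = 10, d = 100, e = 1L), n)
  expect_false(undef$defined)
  expect_true(is.na(undef$s))
})

test_that("the score is monotone in each measure and strictly increasing in e", {
  set.seed(4)
  trials <- data.frame(subject_id = 1, f = runif(20, 1, 9), r = runif(20, 100, 2000),
                       d = runif(20, 1000, 9000), e = rpois(20, 0.5))
  n <- subject_norms(trials)
  base <- grasp_score(list(f = 4, r = 500, d = 4000, e = 1L), n)$s
  expect_gte(grasp_score(list(f = 5, r = 500, d = 4000, e = 1L), n)$s, base)
  expect_gte(grasp_score(list(f = 4, r = 600, d = 4000, e = 1L), n)$s, base)
  expect_gte(grasp_score(list(f = 4, r = 500, d = 5000, e = 1L), n)$s, base)
  expect_gt(grasp_score(list(f = 4, r = 500, d = 4000, e = 2L), n)$s, base)
})

test_that("scores are order-free and invariant to unit rescaling", {
  set.seed(5)
  trials <- data.frame(subject_id = rep(1:2, each = 10),
                       f = runif(20, 1, 9), r = runif(20, 100, 2000),
                       d = runif(20, 1000, 9000), e = rpois(20, 0.5))
  scored <- score_trials(trials)
  perm <- sample(nrow(trials))
  scored_perm <- score_trials(trials[perm, ])
  expect_equal(scored_perm$s[order(perm)], scored$s)

  rescaled <- trials
  rescaled$r <- rescaled$r / 1000  # ms -> s
  expect_equal(score_trials(rescaled)$norm_r, scored$norm_r)
  expect_equal(score_trials(rescaled)$s, scored$s)
})

test_that("the per-measure minimiser among error-free trials bounds the subject minimum", {
  set.seed(6)
  trials <- data.frame(subject_id = 1, f = runif(30, 1, 9),
                       r = runif(30, 100, 2000), d = runif(30, 1000, 9000),
                       e = rpois(30, 0.7))
  scored <- score_trials(trials)
  ok <- scored$e == 0
  # every error-free trial sits at or above its own subject's target on each
  # measure, so error-free scores are non-negative
  expect_true(all(scored$s[ok] >= -1e-9))
  argmins <- unique(c(which.min(replace(scored$f, !ok, Inf)),
                      which.min(replace(scored$r, !ok, Inf)),
                      which.min(replace(scored$d, !ok, Inf))))
  expect_lte(min(scored$s[ok]), min(scored$s[argmins]) + 1e-9)
})

test_that("force saturation during elevation is flagged on measured trials", {
  pol <- subject_policy(c(heavy = 2.5, light = 0.6))  # ~12.8 N, above the sensor range
  tr <- simulate_trial(object_spec("heavy"), policy = pol, seed = 10)
  ms <- sense(tr)
  seg <- segment_trial(ms)
  m <- trial_metrics(ms, seg, no_events)
  expect_true(m$force_saturated)
  expect_equal(m$f, 10, tolerance = 1e-6)
})
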