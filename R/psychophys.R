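# Adaptive-staircase 2IFC psychophysics for the vibrotactile display.
#
# Two stimuli are presented in sequence at nearby forearm locations (display
# units 0-255, wrist to elbow) and the subject reports whether the second was
# to the right or left of the first. A weighted up-down staircase (asymmetric
# steps, step_up = step_down * p/(1-p)) converges on the separation at which
# the proportion correct equals the target p (default 75%). Psychometric
# functions are maximum-likelihood cumulative Gaussians fitted to the raw
# per-trial responses, never to binned data.

#' Ideal-observer model for location discrimination
#'
#' The observer reports "right" with probability
#' `lapse/2 + (1 - lapse) * pnorm((separation - bias) / sigma)`.
#'
#' @param sigma Discrimination noise SD, display units.
#' @param bias Constant response bias, display units.
#' @param lapse_rate Probability of a stimulus-independent random response.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(sigma, bias = 0, lapse_rate = 0) {
  assert_scalar_num(sigma, "sigma", 0, strict = TRUE)
  assert_scalar_num(bias, "bias")
  assert_scalar_num(lapse_rate, "lapse_rate", 0)
  if (lapse_rate >= 0.5) stopf("invariant violated: lapse_rate < 0.5 required")
  structure(list(sigma = sigma, bias = bias, lapse_rate = lapse_rate),
            class = "observer_model")
}

#' Simulate one 2IFC response
#'
#' @param observer An [observer_model()].
#' @param signed_separation Second-stimulus location minus first, display
#'   units (sign encodes side).
#' @param reference_location Reference location carried into the record.
#' @param seed Optional seed for reproducibility.
#' @return One-row data frame: `reference_location`, `signed_separation`,
#'   `response` ("right"/"left"), `correct`.
#' @export
observer_respond <- function(observer, signed_separation,
                             reference_location = 127.5, seed = NULL) {
  stopifnot(inherits(observer, "observer_model"))
  p_right <- observer$lapse_rate / 2 + (1 - observer$lapse_rate) *
    stats::pnorm((signed_separation - observer$bias) / observer$sigma)
  u <- with_seed(seed, stats::runif(length(signed_separation)))
  response <- ifelse(u < p_right, "right", "left")
  correct <- (response == "right") == (signed_separation >= 0)
  data.frame(reference_location = reference_location,
             signed_separation = signed_separation,
             response = response, correct = correct,
             stringsAsFactors = FALSE)
}

#' Staircase configuration
#'
#' Weighted up-down rule: the separation shrinks by the current down-step
#' after a correct response and grows by `step_up = step_down * p / (1 - p)`
#' after an incorrect one, which makes the staircase stationary exactly at
#' proportion-correct `p` (3:1 for the default 75% target). To remove the
#' slow initial descent from a wide starting separation, the down-step starts
#' at `initial_step_down` and halves at every reversal until it reaches
#' `step_down` (the up-step keeps the p/(1-p) ratio throughout, so the
#' equilibrium point never moves); the converged threshold is then estimated
#' from the reversals that occur at the final step size.
#'
#' @param reference_location Reference location, display units on `[0, 255]`.
#' @param target_proportion Targeted proportion correct.
#' @param initial_separation Starting separation, display units.
#' @param step_down Final decrement after a correct response, display units.
#' @param step_up Final increment after an incorrect response; defaults to the
#'   weighted up-down value for `target_proportion`.
#' @param initial_step_down Starting down-step, halved at each reversal until
#'   it reaches `step_down`.
#' @param n_trials Number of stimulus pairs (study: 20 per location).
#' @param min_separation Floor on the separation, display units.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(reference_location = 127.5,
                             target_proportion = 0.75,
                             initial_separation = 60,
                             step_down = 1,
                             step_up = step_down * target_proportion /
                               (1 - target_proportion),
                             initial_step_down = 8 * step_down,
                             n_trials = 20,
                             min_separation = 1) {
  assert_scalar_num(target_proportion, "target_proportion", 0, strict = TRUE)
  if (target_proportion >= 1) stopf("invariant violated: 0 < target_proportion < 1")
  assert_scalar_num(step_down, "step_down", 0, strict = TRUE)
  assert_scalar_num(step_up, "step_up", 0, strict = TRUE)
  assert_scalar_num(initial_step_down, "initial_step_down", 0, strict = TRUE)
  if (initial_step_down < step_down) {
    stopf("initial_step_down must be at least step_down")
  }
  assert_scalar_num(initial_separation, "initial_separation", 0, strict = TRUE)
  assert_scalar_num(n_trials, "n_trials", 1)
  assert_scalar_num(min_separation, "min_separation", 0)
  structure(list(reference_location = reference_location,
                 target_proportion = target_proportion,
                 initial_separation = initial_separation,
                 step_down = step_down, step_up = step_up,
                 initial_step_down = initial_step_down,
                 n_trials = as.integer(n_trials),
                 min_separation = min_separation),
            class = "staircase_config")
}

#' Initialise staircase state
#' @param config A [staircase_config()].
#' @return A `staircase_state` list.
#' @export
staircase_init <- function(config) {
  stopifnot(inherits(config, "staircase_config"))
  structure(list(config = config,
                 separation = config$initial_separation,
                 current_step_down = config$initial_step_down,
                 last_direction = 0L,
                 reversal = FALSE),
            class = "staircase_state")
}

#' One staircase step
#'
#' After a correct response the separation decreases by the current down-step;
#' after an incorrect one it increases by `target/(1 - target)` times that
#' step. A reversal halves the down-step toward its final value
#' (`config$step_down`) before the move is applied.
#'
#' @param state A `staircase_state` from [staircase_init()] or a previous
#'   update.
#' @param correct Logical: was the last response correct?
#' @return The updated state; `state$reversal` is `TRUE` when this step
#'   reversed the direction of movement, and `state$at_final_step` reports
#'   whether the step size had already reached its final value when the
#'   presented trial was generated.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"),
            is.logical(correct), length(correct) == 1L, !is.na(correct))
  cfg <- state$config
  direction <- if (correct) -1L else 1L
  state$reversal <- state$last_direction != 0L && direction != state$last_direction
  state$at_final_step <- state$current_step_down <= cfg$step_down
  if (state$reversal && !state$at_final_step) {
    state$current_step_down <- max(cfg$step_down, state$current_step_down / 2)
  }
  ratio <- cfg$target_proportion / (1 - cfg$target_proportion)
  move <- if (correct) -state$current_step_down else state$current_step_down * ratio
  state$separation <- max(cfg$min_separation, state$separation + move)
  state$last_direction <- direction
  state
}

#' Run one adaptive staircase against a simulated observer
#'
#' @param config A [staircase_config()].
#' @param observer An [observer_model()].
#' @param seed Integer seed; the response draws and stimulus sides are
#'   reproducible under it.
#' @return An object of class `staircase_run`: list with `records` (one row
#'   per trial: separation presented, signed separation, response, correct,
#'   reversal, at_final_step), `threshold` (mean separation over the
#'   final-step-size reversals, excluding the first of them; falls back to the
#'   mean separation of the last half of the trials when fewer than two such
#'   reversals occurred) and `n_reversals`.
#' @export
run_staircase <- function(config, observer, seed = 1L) {
  stopifnot(inherits(config, "staircase_config"),
            inherits(observer, "observer_model"))
  with_seed(seed, {
    state <- staircase_init(config)
    n <- config$n_trials
    rec <- data.frame(trial = seq_len(n), separation = NA_real_,
                      signed_separation = NA_real_,
                      response = NA_character_, correct = NA,
                      reversal = FALSE, at_final_step = FALSE,
                      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      sep <- state$separation
      at_final <- state$current_step_down <= config$step_down
      side <- if (stats::runif(1) < 0.5) 1 else -1
      resp <- observer_respond(observer, side * sep,
                               reference_location = config$reference_location)
      state <- staircase_update(state, resp$correct)
      rec$separation[i] <- sep
      rec$signed_separation[i] <- resp$signed_separation
      rec$response[i] <- resp$response
      rec$correct[i] <- resp$correct
      rec$reversal[i] <- state$reversal
      rec$at_final_step[i] <- at_final
    }
    rev_idx <- which(rec$reversal & rec$at_final_step)
    threshold <- if (length(rev_idx) >= 2L) {
      mean(rec$separation[rev_idx[-1L]])  # discard the first settled reversal
    } else {
      mean(rec$separation[seq.int(max(1L, n %/% 2L), n)])
    }
    structure(list(records = rec, threshold = threshold,
                   n_reversals = sum(rec$reversal), config = config),
              class = "staircase_run")
  })
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf("<staircase_run> %d trials, %d reversals, converged threshold %.2f display units\n",
              nrow(x$records), x$n_reversals, x$threshold))
  invisible(x)
}

#' Maximum-likelihood cumulative-Gaussian psychometric fit
#'
#' Fits `P(right | x) = lapse/2 + (1 - lapse) * pnorm((x - bias) / sigma)` to
#' raw per-trial 2IFC records by maximum likelihood. The adaptive staircase
#' does not give evenly distributed points, so the fit is to the unbinned
#' per-trial responses, never to binned proportions.
#'
#' @param records Data frame with columns `signed_separation` and `response`
#'   (`"right"`/`"left"`), e.g. rows of [run_staircase()] records or pooled
#'   across subjects.
#' @param target_proportion Criterion proportion defining the JND.
#' @param lapse_max Upper bound on the fitted lapse rate; set 0 to fix it.
#' @return An object of class `psychometric_fit` with `coefficients`
#'   (`bias`, `sigma`, `lapse`), `logLik`, `jnd` (the separation above bias at
#'   which the proportion correct reaches `target_proportion`, i.e.
#'   `qnorm(target) * sigma`), `n`, and a `degenerate` flag raised when the
#'   data are perfectly separable and sigma collapses to its lower bound.
#' @export
fit_psychometric <- function(records, target_proportion = 0.75,
                             lapse_max = 0.05) {
  stopifnot(is.data.frame(records),
            all(c("signed_separation", "response") %in% names(records)))
  x <- records$signed_separation
  y <- as.integer(records$response == "right")
  if (length(unique(x)) < 2L) {
    stopf("need at least 2 distinct separations to fit a psychometric function")
  }
  sigma_lo <- 1e-3
  nll <- function(par) {
    bias <- par[1L]; sigma <- exp(par[2L]); lapse <- par[3L]
    p <- lapse / 2 + (1 - lapse) * stats::pnorm((x - bias) / sigma)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  start <- c(0, log(max(stats::sd(x), 1)), min(0.01, lapse_max))
  fit <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(-512, log(sigma_lo), 0),
                      upper = c(512, log(1e4), lapse_max))
  bias <- fit$par[1L]
  sigma <- exp(fit$par[2L])
  lapse <- fit$par[3L]
  degenerate <- sigma <= sigma_lo * 1.01 || length(unique(y)) < 2L
  structure(list(coefficients = c(bias = bias, sigma = sigma, lapse = lapse),
                 logLik = -fit$value,
                 jnd = stats::qnorm(target_proportion) * sigma,
                 target_proportion = target_proportion,
                 n = length(y), degenerate = degenerate,
                 data = data.frame(signed_separation = x, right = y),
                 convergence = fit$convergence),
            class = "psychometric_fit")
}

#' @export
coef.psychometric_fit <- function(object, ...) object$coefficients

#' @export
logLik.psychometric_fit <- function(object, ...) {
  structure(object$logLik, df = 3L, nobs = object$n, class = "logLik")
}

#' Predicted response probabilities from a psychometric fit
#'
#' @param object A `psychometric_fit`.
#' @param newdata Numeric vector of signed separations (or a data frame with a
#'   `signed_separation` column). Defaults to the fitted data.
#' @param type `"right"` for P(report right), `"correct"` for the proportion
#'   correct at an unsigned separation.
#' @param ... Unused.
#' @export
predict.psychometric_fit <- function(object, newdata = NULL,
                                     type = c("right", "correct"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$data$signed_separation
       else if (is.data.frame(newdata)) newdata$signed_separation
       else newdata
  cf <- object$coefficients
  p_right <- function(s) {
    cf[["lapse"]] / 2 + (1 - cf[["lapse"]]) *
      stats::pnorm((s - cf[["bias"]]) / cf[["sigma"]])
  }
  if (type == "right") p_right(x) else (p_right(abs(x)) + 1 - p_right(-abs(x))) / 2
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("<psychometric_fit> n = %d; bias %.2f, sigma %.2f, lapse %.3f; JND(%.0f%%) = %.2f%s\n",
              x$n, cf[["bias"]], cf[["sigma"]], cf[["lapse"]],
              100 * x$target_proportion, x$jnd,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
summary.psychometric_fit <- function(object, ...) {
  cat("Cumulative-Gaussian psychometric fit (maximum likelihood, raw responses)\n")
  print(object)
  cat(sprintf("  log-likelihood %.2f on %d trials\n", object$logLik, object$n))
  invisible(object)
}

#' @export
plot.psychometric_fit <- function(x, bin = 10, ...) {
  d <- x$data
  xs <- seq(min(d$signed_separation), max(d$signed_separation), length.out = 200)
  graphics::plot(xs, predict(x, xs), type = "l",
                 xlab = "signed separation [display units]",
                 ylab = "P(report right)", ylim = c(0, 1), ...)
  o <- order(d$signed_separation)
  grp <- ceiling(seq_along(o) / bin)
  graphics::points(tapply(d$signed_separation[o], grp, mean),
                   tapply(d$right[o], grp, mean), pch = 19, col = 2)
  invisible(x)
}

#' JND profile along the forearm
#'
#' @param locations Reference locations, display units (wrist = 0, elbow =
#'   255), strictly increasing.
#' @param jnds Per-location JNDs, display units, all positive.
#' @param span Display span of the array.
#' @return An object of class `jnd_profile` with the discriminable-level count
#'   precomputed as `n_levels`.
#' @export
jnd_profile <- function(locations, jnds, span = c(0, 255)) {
  stopifnot(length(locations) == length(jnds), length(locations) >= 1L)
  if (is.unsorted(locations, strictly = TRUE)) {
    stopf("locations must be strictly increasing")
  }
  if (any(jnds <= 0)) stopf("invariant violated: jnds > 0 required")
  prof <- structure(list(locations = locations, jnds = jnds, span = span),
                    class = "jnd_profile")
  prof$n_levels <- discriminable_levels(prof, span)
  prof
}

#' Count of discriminable stimulus levels over the display span
#'
#' Greedy walk from the wrist: place the first stimulus at the start of the
#' span, then repeatedly step forward by the locally interpolated JND (linear
#' interpolation between reference locations, constant beyond the ends) until
#' the next stimulus would exceed the span. The count is the number of
#' stimuli placed.
#'
#' @param profile A [jnd_profile()].
#' @param span Numeric length-2 span to walk, display units.
#' @return Integer count of placeable, pairwise-distinguishable stimuli.
#' @export
discriminable_levels <- function(profile, span = c(0, 255)) {
  stopifnot(inherits(profile, "jnd_profile"))
  if (any(profile$jnds <= 0)) stopf("non-positive JND rejected")
  jnd_at <- function(x) {
    if (length(profile$locations) == 1L) return(rep(profile$jnds, length(x)))
    stats::approx(profile$locations, profile$jnds, xout = x, rule = 2)$y
  }
  x <- span[1L]
  count <- 1L
  repeat {
    step <- jnd_at(x)
    if (step <= 0) stopf("non-positive JND rejected")
    x <- x + step
    if (x > span[2L] + 1e-9) break
    count <- count + 1L
  }
  count
}

#' @export
print.jnd_profile <- function(x, ...) {
  cat(sprintf("<jnd_profile> %d locations; JND %.1f-%.1f display units; %d discriminable levels\n",
              length(x$locations), min(x$jnds), max(x$jnds), x$n_levels))
  invisible(x)
}

#' Simulate the preliminary JND study
#'
#' Runs one adaptive staircase per subject and reference location against
#' per-subject simulated observers, emulating the preliminary experiment (6
#' subjects, 6 reference locations from wrist to elbow, 20 stimulus pairs per
#' location).
#'
#' @param n_subjects Number of simulated subjects.
#' @param locations Reference locations, display units.
#' @param sigma Median observer discrimination SD, display units; per-subject
#'   sigmas are jittered around it (lognormal, 15% CV).
#' @param n_trials Stimulus pairs per location.
#' @param seed Root seed.
#' @return Data frame of response records with `subject_id` and
#'   `reference_location` columns, suitable for pooled [fit_psychometric()]
#'   per location.
#' @export
simulate_jnd_study <- function(n_subjects = 6,
                               locations = seq(0, 255, length.out = 6),
                               sigma = 20, n_trials = 20, seed = 1L) {
  sigmas <- with_seed(derive_seed(seed, "observers"),
                      sigma * exp(stats::rnorm(n_subjects, 0, 0.15)))
  out <- list()
  for (s in seq_len(n_subjects)) {
    obs <- observer_model(sigma = sigmas[s])
    for (li in seq_along(locations)) {
      cfg <- staircase_config(reference_location = locations[li],
                              n_trials = n_trials)
      run <- run_staircase(cfg, obs,
                           seed = derive_seed(seed, sprintf("s%d_l%d", s, li)))
      rec <- run$records
      rec$subject_id <- s
      rec$reference_location <- locations[li]
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}
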