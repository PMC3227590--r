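# Internal utilities: seeded RNG streams and minimum-jerk kinematics.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number state.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      get(".Random.seed", envir = .GlobalEnv)
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
          rm(".Random.seed", envir = .GlobalEnv)
        }
      } else {
        assign(".Random.seed", old, envir = .GlobalEnv)
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministically derive an independent substream seed (< 2^31) from a root
# seed and a stream label, so the delay, sensor-noise and policy draws of one
# trial do not share a stream.
#' @noRd
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629L + 1)
}

# Minimum-jerk position profile from 0 to `amplitude` over `duration`,
# evaluated at times `t` past onset (clamped outside [0, duration]).
#' @noRd
min_jerk_pos <- function(t, amplitude, duration) {
  tau <- pmin(pmax(t / duration, 0), 1)
  amplitude * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' @noRd
min_jerk_vel <- function(t, amplitude, duration) {
  tau <- pmin(pmax(t / duration, 0), 1)
  inside <- t >= 0 & t <= duration
  (amplitude / duration) * (30 * tau^2 - 60 * tau^3 + 30 * tau^4) * inside
}

#' @noRd
min_jerk_acc <- function(t, amplitude, duration) {
  tau <- pmin(pmax(t / duration, 0), 1)
  inside <- t >= 0 & t <= duration
  (amplitude / duration^2) * (60 * tau - 180 * tau^2 + 120 * tau^3) * inside
}

# Peak upward acceleration of a minimum-jerk lift (used for the dynamic
# slip threshold): max of 60*tau - 180*tau^2 + 120*tau^3 is 10/sqrt(3).
#' @noRd
min_jerk_peak_acc <- function(amplitude, duration) {
  amplitude / duration^2 * 10 / sqrt(3)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("'%s' must be a single non-missing number", name)
  }
  if (strict && x <= min) stopf("invariant violated: %s > %g required (got %g)", name, min, x)
  if (!strict && x < min) stopf("invariant violated: %s >= %g required (got %g)", name, min, x)
  invisible(x)
}
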