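# Per-trial performance measures and the compound grasp score.
#
# For trial i the measures are
#   f_i - mean grip force (N) over the object's elevation,
#   r_i - force-ramp duration (ms), excluding injected pre-ramp delay,
#   d_i - trial duration (ms), excluding all injected delays,
#   e_i - number of (de-duplicated) errors,
# and the compound score is
#   s_i = norm(f, i) + norm(r, i) + norm(d, i) + e_i,
#   norm(x, i) = (x_i - target(x)) / (peak(x) - target(x)),
#   target(x) = min_j { x_j | e_j = 0 },   peak(x) = max_j x_j,
# with target/peak taken per subject. s = 0 marks the subject's best
# performance; higher is worse, and each error adds a full unit.

#' Per-trial performance measures
#'
#' @param traj A `grasp_trajectory` (the channel actually recorded, i.e. the
#'   [sense()]d trajectory in a realistic pipeline).
#' @param seg The matching [segment_trial()] result.
#' @param errors The matching [detect_errors()] result.
#' @param trial_id,subject_id Identifiers carried into the output row.
#' @param condition Optional named list of condition labels (object weight,
#'   feedback condition, block, phase, ...) appended as columns.
#' @return A one-row data frame of class `trial_metrics` with columns
#'   `trial_id`, `subject_id`, any condition labels, `f` (N), `r` (ms),
#'   `d` (ms), `e` (count), and logical flags `f_defined`, `r_defined`,
#'   `force_saturated`.
#' @export
trial_metrics <- function(traj, seg, errors,
                          trial_id = 1L, subject_id = 1L,
                          condition = list()) {
  stopifnot(inherits(seg, "segmented_trial"))
  delays <- traj$injected_delays
  pre_ramp_delay <- if (!is.null(delays) && nrow(delays)) {
    sum(delays$duration[delays$insertion_point == "pre_ramp"])
  } else 0
  total_delay <- if (!is.null(delays) && nrow(delays)) sum(delays$duration) else 0

  # f: mean grip force over the elevation interval(s)
  f_defined <- nrow(seg$elevation_intervals) > 0L
  f <- NA_real_
  force_saturated <- FALSE
  if (f_defined) {
    tf <- traj$force$time
    sel <- rep(FALSE, length(tf))
    for (i in seq_len(nrow(seg$elevation_intervals))) {
      sel <- sel | (tf >= seg$elevation_intervals$start[i] &
                      tf <= seg$elevation_intervals$end[i])
    }
    f <- mean(traj$force$force[sel])
    if (isTRUE(traj$measured) && !is.null(traj$sensors)) {
      force_saturated <- any(traj$force$force[sel] >=
                               traj$sensors$force_linear_max - 1e-9)
    }
  }

  r_defined <- !is.na(seg$ramp_start) && !is.na(seg$ramp_end)
  r <- if (r_defined) {
    max(0, (seg$ramp_end - seg$ramp_start - pre_ramp_delay)) * 1000
  } else NA_real_
  d <- (seg$trial_end - seg$trial_start - total_delay) * 1000
  e <- nrow(errors)

  row <- data.frame(trial_id = trial_id, subject_id = subject_id,
                    stringsAsFactors = FALSE)
  for (nm in names(condition)) row[[nm]] <- condition[[nm]]
  row$f <- f
  row$r <- r
  row$d <- d
  row$e <- as.integer(e)
  row$f_defined <- f_defined
  row$r_defined <- r_defined
  row$force_saturated <- force_saturated
  class(row) <- c("trial_metrics", "data.frame")
  row
}

#' Per-subject normalisation constants
#'
#' `target(x)` is the subject's best (minimum) value of measure `x` over
#' error-free trials only; `peak(x)` is the worst (maximum) over all trials.
#' If the subject has no error-free trials the target falls back to the
#' minimum over all trials and the result is flagged.
#'
#' @param trials Data frame of per-trial measures with columns `f`, `r`, `d`,
#'   `e` (one subject's trials).
#' @return An object of class `subject_norms`: list with numeric vectors
#'   `target` and `peak` (named `f`, `r`, `d`) and flag `no_error_free`.
#' @export
subject_norms <- function(trials) {
  stopifnot(is.data.frame(trials), all(c("f", "r", "d", "e") %in% names(trials)),
            nrow(trials) >= 1L)
  measures <- c("f", "r", "d")
  ok <- trials$e == 0
  no_error_free <- !any(ok, na.rm = TRUE)
  target <- vapply(measures, function(m) {
    x <- trials[[m]][if (no_error_free) TRUE else ok]
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  }, numeric(1))
  peak <- vapply(measures, function(m) {
    x <- trials[[m]]
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  }, numeric(1))
  structure(list(target = target, peak = peak, no_error_free = no_error_free),
            class = "subject_norms")
}

#' @export
print.subject_norms <- function(x, ...) {
  cat("<subject_norms>", if (x$no_error_free) "(no error-free trials: target is a fallback)\n" else "\n")
  print(rbind(target = x$target, peak = x$peak))
  invisible(x)
}

#' Normalise a measure into the subject's target-peak range
#'
#' Linear map sending `target` to 0 and `peak` to 1. Values below target give
#' negative norms (retained, not clipped). If `peak == target` every trial is
#' equally good and the norm is 0 by convention.
#'
#' @param x Measure value(s).
#' @param norms A [subject_norms()] object.
#' @param measure One of `"f"`, `"r"`, `"d"`.
#' @return Dimensionless normalised value(s).
#' @export
normalize_measure <- function(x, norms, measure = c("f", "r", "d")) {
  stopifnot(inherits(norms, "subject_norms"))
  measure <- match.arg(measure)
  tg <- norms$target[[measure]]
  pk <- norms$peak[[measure]]
  if (is.na(tg) || is.na(pk)) return(rep(NA_real_, length(x)))
  if (pk == tg) return(ifelse(is.na(x), NA_real_, 0))
  (x - tg) / (pk - tg)
}

#' Compound grasp score of a trial
#'
#' `s = norm(f) + norm(r) + norm(d) + e`; higher is worse. If any component is
#' undefined (e.g. `f` on a trial whose object was never elevated) the score
#' is returned as `NA` with `defined = FALSE`, never silently imputed.
#'
#' @param metrics A one-row [trial_metrics()] data frame (or any list with
#'   `f`, `r`, `d`, `e`).
#' @param norms The subject's [subject_norms()].
#' @return An object of class `grasp_score`: list with `s`, `components`
#'   (norm_f, norm_r, norm_d, e) and `defined`.
#' @export
grasp_score <- function(metrics, norms) {
  stopifnot(inherits(norms, "subject_norms"))
  nf <- normalize_measure(metrics$f, norms, "f")
  nr <- normalize_measure(metrics$r, norms, "r")
  nd <- normalize_measure(metrics$d, norms, "d")
  e <- metrics$e
  s <- nf + nr + nd + e
  structure(list(s = s,
                 components = c(norm_f = nf, norm_r = nr, norm_d = nd, e = e),
                 defined = !is.na(s)),
            class = "grasp_score")
}

#' @export
print.grasp_score <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<grasp_score> s = %.4f  (norm_f %.3f + norm_r %.3f + norm_d %.3f + e %d)\n",
                x$s, x$components[["norm_f"]], x$components[["norm_r"]],
                x$components[["norm_d"]], as.integer(x$components[["e"]])))
  } else {
    cat("<grasp_score> undefined (a component measure is missing)\n")
  }
  invisible(x)
}

#' Score a table of trials with per-subject normalisation
#'
#' Computes [subject_norms()] within each subject and appends the component
#' norms and the compound score `s` to the table. Norms are order-free:
#' shuffling the trials gives identical scores.
#'
#' @param trials Data frame with columns `subject_id`, `f`, `r`, `d`, `e`.
#' @return The table with added columns `norm_f`, `norm_r`, `norm_d`, `s` and
#'   `norms_fallback` (TRUE when the subject had no error-free trials).
#' @export
score_trials <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("subject_id", "f", "r", "d", "e") %in% names(trials)))
  trials$norm_f <- NA_real_
  trials$norm_r <- NA_real_
  trials$norm_d <- NA_real_
  trials$s <- NA_real_
  trials$norms_fallback <- FALSE
  for (sid in unique(trials$subject_id)) {
    idx <- trials$subject_id == sid
    norms <- subject_norms(trials[idx, , drop = FALSE])
    trials$norm_f[idx] <- normalize_measure(trials$f[idx], norms, "f")
    trials$norm_r[idx] <- normalize_measure(trials$r[idx], norms, "r")
    trials$norm_d[idx] <- normalize_measure(trials$d[idx], norms, "d")
    trials$s[idx] <- trials$norm_f[idx] + trials$norm_r[idx] +
      trials$norm_d[idx] + trials$e[idx]
    trials$norms_fallback[idx] <- norms$no_error_free
  }
  trials
}
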