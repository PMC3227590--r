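# Block/condition structures of the three feedback experiments and the
# simulated-cohort runner that composes simulate -> sense -> segment ->
# detect -> score into tidy per-trial tables.
#
# Experiment 1: ideal conditions; visual feedback throughout, vibrotactile
#   feedback alternating between blocks (counterbalanced, 2 orders); 4 blocks
#   of 20 heavy + 20 light trials.
# Experiment 2: sensory deprivation; two between-subject groups (veridical
#   vibrotactile vs uncorrelated random stimuli); 3 blocks of 12 + 12 trials,
#   the third in darkness (visual channel removed).
# Experiment 3: feedforward uncertainty; random controller delays U(0, 1.5) s
#   at movement onset and ramp onset; heavy object only; four feedback
#   conditions (none / tactile / visual / both) x 12 trials, repeated over two
#   phases; condition orders counterbalanced across four groups.

#' Build one of the three experiment designs
#'
#' @param experiment_id 1, 2 or 3.
#' @return An object of class `experiment_design`: the per-block condition
#'   table template, counterbalancing orders (assigned to subjects cyclically),
#'   the delay specification, and the study's default cohort sizes.
#' @examples
#' build_design(1)
#' @export
build_design <- function(experiment_id) {
  if (!length(experiment_id) == 1L || !experiment_id %in% 1:3) {
    stopf("unknown experiment id: %s (must be 1, 2 or 3)", toString(experiment_id))
  }
  experiment_id <- as.integer(experiment_id)
  if (experiment_id == 1L) {
    blocks <- data.frame(block = 1:4, phase = 1L, visual = TRUE,
                         tactile = NA, n_heavy = 20L, n_light = 20L)
    counterbalancing <- list(
      list(tactile = c(TRUE, FALSE, TRUE, FALSE)),
      list(tactile = c(FALSE, TRUE, FALSE, TRUE))
    )
    dspec <- delay_spec(enabled = FALSE)
    n_default <- 6L
  } else if (experiment_id == 2L) {
    blocks <- data.frame(block = 1:3, phase = 1L,
                         visual = c(TRUE, TRUE, FALSE),
                         tactile = NA, n_heavy = 12L, n_light = 12L)
    counterbalancing <- list(
      list(group = "tactile", tactile = c(TRUE, TRUE, TRUE)),
      list(group = "random", tactile = c(FALSE, FALSE, FALSE))
    )
    dspec <- delay_spec(enabled = FALSE)
    n_default <- 12L
  } else {
    base <- data.frame(block = 1:4, n_heavy = 12L, n_light = 0L)
    blocks <- rbind(cbind(base, phase = 1L), cbind(transform(base, block = block + 4L), phase = 2L))
    blocks$visual <- NA
    blocks$tactile <- NA
    blocks <- blocks[, c("block", "phase", "visual", "tactile", "n_heavy", "n_light")]
    # 2 x 2 counterbalancing of visual order and tactile order; each phase
    # presents all four feedback configurations
    counterbalancing <- list()
    for (v_first in c(TRUE, FALSE)) {
      for (t_first in c(TRUE, FALSE)) {
        vis <- if (v_first) c(TRUE, TRUE, FALSE, FALSE) else c(FALSE, FALSE, TRUE, TRUE)
        tac <- if (t_first) c(TRUE, FALSE, TRUE, FALSE) else c(FALSE, TRUE, FALSE, TRUE)
        counterbalancing[[length(counterbalancing) + 1L]] <-
          list(visual = rep(vis, 2L), tactile = rep(tac, 2L))
      }
    }
    dspec <- delay_spec(enabled = TRUE, low = 0, high = 1.5)
    n_default <- 12L
  }
  structure(list(experiment_id = experiment_id, blocks = blocks,
                 counterbalancing = counterbalancing, delay_spec = dspec,
                 n_subjects_default = n_default),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  n_trials <- sum(x$blocks$n_heavy + x$blocks$n_light)
  cat(sprintf("<experiment_design %d> %d blocks, %d trials per subject, %d counterbalancing order(s), delays %s\n",
              x$experiment_id, nrow(x$blocks), n_trials,
              length(x$counterbalancing),
              if (x$delay_spec$enabled) "on" else "off"))
  invisible(x)
}

#' Simulated cohort specification
#'
#' @param n_subjects Number of simulated subjects.
#' @param seed Root seed; every per-subject draw and per-trial stream is
#'   derived from it.
#' @param feedback_gain Within-trial feedback correction gain given to the
#'   subjects (applies whenever a feedback channel is present).
#' @param perceptual_noise_sd Perceived-force noise SD, N.
#' @param planned_ramp_duration Initial planned flexor holds, named by object.
#' @param planned_jitter_sd Lognormal SD of the per-subject jitter applied to
#'   the initial plans (individual differences).
#' @param early_release_prob Per-trial probability of a mid-hold grip mishap.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, seed = 1L,
                        feedback_gain = 1,
                        perceptual_noise_sd = 0.3,
                        planned_ramp_duration = c(heavy = 1.1, light = 0.7),
                        planned_jitter_sd = 0.1,
                        early_release_prob = 0.02) {
  assert_scalar_num(n_subjects, "n_subjects", 0)
  structure(list(n_subjects = as.integer(n_subjects), seed = seed,
                 feedback_gain = feedback_gain,
                 perceptual_noise_sd = perceptual_noise_sd,
                 planned_ramp_duration = planned_ramp_duration,
                 planned_jitter_sd = planned_jitter_sd,
                 early_release_prob = early_release_prob),
            class = "cohort_spec")
}

#' @noRd
cohort_policy <- function(cohort, subject) {
  jit <- with_seed(derive_seed(cohort$seed, paste0("subject_policy_", subject)),
                   exp(stats::rnorm(length(cohort$planned_ramp_duration), 0,
                                    cohort$planned_jitter_sd)))
  planned <- cohort$planned_ramp_duration * jit
  subject_policy(planned_ramp_duration = planned,
                 feedback_gain = cohort$feedback_gain,
                 perceptual_noise_sd = cohort$perceptual_noise_sd,
                 early_release_prob = cohort$early_release_prob)
}

#' Run an experiment design on a simulated cohort
#'
#' Composes the full pipeline per trial - [simulate_trial()], [sense()],
#' [segment_trial()], [detect_errors()], [trial_metrics()] - with
#' trial-to-trial policy adaptation ([adapt_subject_policy()]) driven by the
#' end-of-trial peak-force display and the detected errors, then applies
#' per-subject normalisation ([score_trials()]).
#'
#' Condition semantics: `visual`/`tactile` toggle the corresponding channel in
#' the subject's within-trial feedback set; the end-of-trial peak-force
#' display (and hence learning) is always available, matching the protocol of
#' all three experiments. The random-stimulus control group of Experiment 2
#' receives no veridical tactile channel.
#'
#' @param design An [build_design()] result.
#' @param cohort A [cohort_spec()].
#' @param object_heavy,object_light Objects used for the weight conditions.
#' @param controller A [controller_config()].
#' @param sensors A [sensor_config()].
#' @return Tidy data frame: one row per trial with identifiers, condition
#'   labels (`group`, `block`, `phase`, `object`, `visual`, `tactile`),
#'   measures `f`, `r`, `d`, `e`, component norms and the grasp score `s`.
#' @export
run_experiment <- function(design, cohort,
                           object_heavy = object_spec("heavy"),
                           object_light = object_spec("light"),
                           controller = controller_config(),
                           sensors = sensor_config()) {
  stopifnot(inherits(design, "experiment_design"), inherits(cohort, "cohort_spec"))
  if (cohort$n_subjects == 0L) {
    out <- data.frame(trial_id = integer(), subject_id = integer(),
                      group = integer(), block = integer(), phase = integer(),
                      object = character(), visual = logical(),
                      tactile = logical(), f = numeric(), r = numeric(),
                      d = numeric(), e = integer())
    return(out)
  }
  n_orders <- length(design$counterbalancing)
  rows <- list()
  for (subj in seq_len(cohort$n_subjects)) {
    order_id <- ((subj - 1L) %% n_orders) + 1L
    cb <- design$counterbalancing[[order_id]]
    policy <- cohort_policy(cohort, subj)
    history <- data.frame(object = character(), planned = numeric(),
                          e = integer(), stringsAsFactors = FALSE)
    trial_no <- 0L
    for (b in seq_len(nrow(design$blocks))) {
      blk <- design$blocks[b, ]
      visual <- if (is.na(blk$visual)) cb$visual[b] else blk$visual
      tactile <- if (is.na(blk$tactile)) cb$tactile[b] else blk$tactile
      channels <- c(if (isTRUE(visual)) "visual",
                    if (isTRUE(tactile)) "vibrotactile")
      objs <- c(rep("heavy", blk$n_heavy), rep("light", blk$n_light))
      objs <- with_seed(derive_seed(cohort$seed, sprintf("order_s%d_b%d", subj, b)),
                        sample(objs))
      for (obj_name in objs) {
        trial_no <- trial_no + 1L
        object <- if (obj_name == "heavy") object_heavy else object_light
        policy$feedback_channels <- channels
        planned_used <- policy$planned_ramp_duration[[obj_name]]
        traj <- simulate_trial(object, controller, design$delay_spec, sensors,
                               policy,
                               seed = derive_seed(cohort$seed,
                                                  sprintf("s%d_t%d", subj, trial_no)))
        meas <- sense(traj, sensors,
                      seed = derive_seed(cohort$seed,
                                         sprintf("noise_s%d_t%d", subj, trial_no)))
        seg <- segment_trial(meas)
        errs <- detect_errors(meas)
        m <- trial_metrics(meas, seg, errs, trial_id = trial_no,
                           subject_id = subj,
                           condition = list(group = order_id, block = blk$block,
                                            phase = blk$phase, object = obj_name,
                                            visual = isTRUE(visual),
                                            tactile = isTRUE(tactile)))
        rows[[length(rows) + 1L]] <- m
        history <- rbind(history,
                         data.frame(object = obj_name, planned = planned_used,
                                    e = m$e, stringsAsFactors = FALSE))
        policy <- adapt_subject_policy(policy, history)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  score_trials(as.data.frame(tab))
}

#' Weight-discrimination contrast
#'
#' Per feedback condition, the difference in a measure between the heavy and
#' the lightweight object (`mean_heavy - mean_light`) with its standard error.
#' A positive contrast on grip force indicates economical discrimination of
#' the two weights.
#'
#' @param table A per-trial table from [run_experiment()] (needs an `object`
#'   column with values `"heavy"`/`"light"`).
#' @param measure Column to contrast (default `"f"`).
#' @param by Condition columns defining the cells.
#' @return Data frame with one row per condition: `contrast`, `se`,
#'   `n_heavy`, `n_light`, and a `missing_cell` flag where a weight is absent
#'   (contrast left `NA`, never imputed).
#' @export
weight_discrimination <- function(table, measure = "f",
                                  by = intersect(c("visual", "tactile"),
                                                 names(table))) {
  stopifnot(is.data.frame(table), "object" %in% names(table),
            measure %in% names(table))
  if (!any(table$object == "heavy") || !any(table$object == "light")) {
    stopf("table must contain both object weights for a discrimination contrast")
  }
  cells <- if (length(by)) unique(table[, by, drop = FALSE]) else data.frame(row.names = 1)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(table))
    for (col in by) sel <- sel & table[[col]] == cells[[col]][i]
    xh <- table[[measure]][sel & table$object == "heavy"]
    xl <- table[[measure]][sel & table$object == "light"]
    xh <- xh[!is.na(xh)]; xl <- xl[!is.na(xl)]
    missing_cell <- length(xh) == 0L || length(xl) == 0L
    contrast <- if (missing_cell) NA_real_ else mean(xh) - mean(xl)
    se <- if (missing_cell || length(xh) < 2L || length(xl) < 2L) NA_real_ else {
      sqrt(stats::var(xh) / length(xh) + stats::var(xl) / length(xl))
    }
    row <- cells[i, , drop = FALSE]
    row$contrast <- contrast
    row$se <- se
    row$n_heavy <- length(xh)
    row$n_light <- length(xl)
    row$missing_cell <- missing_cell
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
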