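# Plain-text interchange: long-format trajectory CSV with a JSON sidecar
# carrying configuration, seed, injected delays and ground truth.
#
# CSV columns: time_s, channel, value1, value2, value3. Channels: force
# (value1 = N), pos_thumb / pos_finger / pos_wrist / pos_object (x, y, z in
# m), aperture (m), flexor / extensor (binary).

.marker_channel <- c(thumb_tip = "pos_thumb", forefinger = "pos_finger",
                     wrist = "pos_wrist", object_base = "pos_object")

#' Write a trajectory to CSV (+ JSON sidecar)
#'
#' @param traj A `grasp_trajectory`.
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param sidecar Write the sidecar JSON (configs, seed, delays, ground
#'   truth)?
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "grasp_trajectory"))
  blk <- function(time, channel, v1, v2 = NA_real_, v3 = NA_real_) {
    data.frame(time_s = time, channel = channel, value1 = v1, value2 = v2,
               value3 = v3, stringsAsFactors = FALSE)
  }
  parts <- list(blk(traj$force$time, "force", traj$force$force))
  for (mk in names(.marker_channel)) {
    p <- traj$positions[[mk]]
    parts[[length(parts) + 1L]] <- blk(p$time, .marker_channel[[mk]], p$x, p$y, p$z)
  }
  parts[[length(parts) + 1L]] <- blk(traj$aperture$time, "aperture",
                                     traj$aperture$aperture)
  parts[[length(parts) + 1L]] <- blk(traj$control$time, "flexor",
                                     traj$control$flexor)
  parts[[length(parts) + 1L]] <- blk(traj$control$time, "extensor",
                                     traj$control$extensor)
  out <- do.call(rbind, parts)
  utils::write.csv(out, path, row.names = FALSE)
  if (sidecar) {
    side <- list(
      object = unclass(traj$object),
      controller = unclass(traj$controller),
      sensors = unclass(traj$sensors),
      seed = traj$seed,
      measured = isTRUE(traj$measured),
      injected_delays = traj$injected_delays,
      ground_truth = traj$ground_truth
    )
    jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  }
  invisible(path)
}

#' @noRd
sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read a trajectory written by [write_trajectory_csv()]
#'
#' @param path CSV path; the `.json` sidecar is read if present.
#' @return A `grasp_trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  pick <- function(ch) d[d$channel == ch, , drop = FALSE]
  f <- pick("force")
  positions <- lapply(names(.marker_channel), function(mk) {
    p <- pick(.marker_channel[[mk]])
    data.frame(time = p$time_s, x = p$value1, y = p$value2, z = p$value3)
  })
  names(positions) <- names(.marker_channel)
  ap <- pick("aperture")
  fl <- pick("flexor")
  ex <- pick("extensor")
  traj <- list(
    force = data.frame(time = f$time_s, force = f$value1),
    positions = positions,
    aperture = data.frame(time = ap$time_s, aperture = ap$value1),
    control = data.frame(time = fl$time_s, flexor = fl$value1,
                         extensor = ex$value1),
    injected_delays = data.frame(insertion_point = character(),
                                 duration = numeric()),
    ground_truth = NULL, object = NULL, controller = NULL, sensors = NULL,
    seed = NULL, measured = NA
  )
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    traj$object <- do.call(object_spec,
                           c(list(name = side$object$name),
                             side$object[c("mass", "contact_diameter",
                                           "friction_coefficient",
                                           "baseline_height")]))
    traj$controller <- do.call(controller_config, side$controller)
    traj$sensors <- do.call(sensor_config, side$sensors)
    traj$seed <- side$seed
    traj$measured <- isTRUE(side$measured)
    if (!is.null(side$injected_delays) && length(side$injected_delays)) {
      traj$injected_delays <- as.data.frame(side$injected_delays)
    }
    gt <- side$ground_truth
    if (!is.null(gt)) {
      if (!is.null(gt$events) && length(gt$events)) {
        gt$events <- as.data.frame(gt$events)
      } else {
        gt$events <- data.frame(kind = character(), time = numeric())
      }
      traj$ground_truth <- gt
    }
  }
  class(traj) <- "grasp_trajectory"
  traj
}

#' Write a segmentation result (with events) to JSON
#'
#' @param seg A [segment_trial()] result.
#' @param events A [detect_errors()] result (optional).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_segmentation_json <- function(seg, events = NULL, path) {
  stopifnot(inherits(seg, "segmented_trial"))
  payload <- unclass(seg)
  payload$phase_labels <- NULL  # per-sample labels stay in R; keep the JSON light
  if (!is.null(events)) payload$events <- as.data.frame(events)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write a per-trial metrics table to CSV
#'
#' @param table A table from [run_experiment()] / [score_trials()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
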