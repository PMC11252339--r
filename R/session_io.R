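#' Write a session bundle to plain-text files
#'
#' Serialises one session as four CSVs plus a ground-truth JSON:
#' `trajectories.csv` (trial_id, t_s, x_cm, y_cm),
#' `events.csv` (trial_id, cell_id, t_s, weight),
#' `trials.csv` (trial metadata incl. dig sequence and reward corner),
#' `cells.csv` (cell id, class, field center), and
#' `ground_truth.json` (ensemble orientations, per-cell applied rotations,
#' classes, gain, coherence).
#'
#' @param bundle A `session_bundle` from [generate_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  traj <- do.call(rbind, lapply(names(bundle$trajectories), function(id) {
    tr <- bundle$trajectories[[id]]
    data.frame(trial_id = id, t_s = tr$t, x_cm = tr$x, y_cm = tr$y)
  }))
  utils::write.csv(traj, file.path(dir, "trajectories.csv"),
                   row.names = FALSE)

  ev <- do.call(rbind, lapply(names(bundle$activity), function(id) {
    per_cell <- bundle$activity[[id]]
    do.call(rbind, lapply(names(per_cell), function(cid) {
      tr <- per_cell[[cid]]
      if (nrow(tr) == 0L) return(NULL)
      data.frame(trial_id = id, cell_id = cid, t_s = tr$t, weight = tr$w)
    }))
  }))
  if (is.null(ev)) {
    ev <- data.frame(trial_id = character(), cell_id = character(),
                     t_s = numeric(), weight = numeric())
  }
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(bundle$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)

  gt <- bundle$ground_truth
  jsonlite::write_json(list(
    animal = bundle$animal, day = bundle$day,
    ensemble_orientation = as.list(gt$ensemble_orientation),
    applied_rotation = apply(gt$applied_rotation, 1L, identity,
                             simplify = FALSE),
    cell_class = as.list(gt$cell_class),
    rate_gain = gt$rate_gain, coherence = gt$coherence
  ), file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session bundle written by [write_session_bundle()]
#'
#' @param dir Directory holding the bundle files.
#' @return A `session_bundle` equivalent to the one written (trajectory
#'   speeds are recomputed from positions).
#' @export
read_session_bundle <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  cells <- utils::read.csv(file.path(dir, "cells.csv"),
                           stringsAsFactors = FALSE)
  traj_df <- utils::read.csv(file.path(dir, "trajectories.csv"),
                             stringsAsFactors = FALSE)
  ev <- utils::read.csv(file.path(dir, "events.csv"),
                        stringsAsFactors = FALSE)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)

  trajectories <- lapply(split(traj_df, factor(traj_df$trial_id,
                                               levels = trials$trial_id)),
                         function(d) {
    tr <- data.frame(t = d$t_s, x = d$x_cm, y = d$y_cm)
    tr$speed <- frame_speed(tr)
    class(tr) <- c("trajectory", "data.frame")
    tr
  })
  activity <- lapply(trials$trial_id, function(id) {
    sub <- ev[ev$trial_id == id, , drop = FALSE]
    out <- lapply(cells$cell_id, function(cid) {
      s <- sub[sub$cell_id == cid, , drop = FALSE]
      tr <- data.frame(t = s$t_s, w = s$weight)
      class(tr) <- c("activity_train", "data.frame")
      tr
    })
    names(out) <- cells$cell_id
    out
  })
  names(activity) <- trials$trial_id

  rot <- do.call(rbind, gt$applied_rotation)
  dimnames(rot) <- list(cells$cell_id, trials$trial_id)
  structure(list(
    animal = gt$animal, day = gt$day, trials = trials,
    trajectories = trajectories, activity = activity, cells = cells,
    ground_truth = list(
      ensemble_orientation = unlist(gt$ensemble_orientation),
      applied_rotation = rot,
      cell_class = unlist(gt$cell_class),
      rate_gain = gt$rate_gain, coherence = gt$coherence
    )
  ), class = "session_bundle")
}
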