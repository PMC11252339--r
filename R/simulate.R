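#' Simulate a confined open-field trajectory
#'
#' Bounded correlated random walk: Ornstein-Uhlenbeck velocity in each
#' coordinate, integrated and folded back into the chamber by reflection.
#' The stationary speed distribution is Rayleigh-like with a tail below the
#' 2 cm/s movement threshold, so downstream speed filtering is exercised.
#'
#' @param config A [sim_config()].
#' @param trial_seed Integer seed for this trial's stream.
#' @param tau_s Velocity autocorrelation time constant (s).
#' @param speed_sd_cm_s Stationary per-axis velocity standard deviation
#'   (cm/s). Zero gives a stationary animal (all speeds 0).
#' @return A `trajectory`: data.frame with columns `t` (s, strictly
#'   increasing), `x`, `y` (cm, inside the chamber) and `speed` (cm/s).
#' @examples
#' cfg <- sim_config(trial_duration_s = 10)
#' tr <- simulate_trajectory(cfg, trial_seed = 7)
#' range(tr$x); range(tr$y)
#' @export
simulate_trajectory <- function(config, trial_seed,
                                tau_s = 1, speed_sd_cm_s = 6) {
  validate_sim_config(config)
  if (config$trial_duration_s <= 0 || config$frame_rate_hz <= 0) {
    stop("trial duration and frame rate must be positive", call. = FALSE)
  }
  dt <- 1 / config$frame_rate_hz
  n <- floor(config$trial_duration_s * config$frame_rate_hz)
  lx <- config$chamber_x_cm
  ly <- config$chamber_y_cm

  withr_seed(trial_seed, {
    x0 <- stats::runif(1, 0.1 * lx, 0.9 * lx)
    y0 <- stats::runif(1, 0.1 * ly, 0.9 * ly)
    if (speed_sd_cm_s <= 0) {
      x <- rep(x0, n); y <- rep(y0, n)
    } else {
      rho <- exp(-dt / tau_s)
      innov_sd <- speed_sd_cm_s * sqrt(1 - rho^2)
      vx <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                     rho, method = "recursive"))
      vy <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                     rho, method = "recursive"))
      x <- reflect_fold(x0 + cumsum(vx * dt), lx)
      y <- reflect_fold(y0 + cumsum(vy * dt), ly)
    }
    t <- (seq_len(n) - 1) * dt
    traj <- data.frame(t = t, x = x, y = y)
    traj$speed <- frame_speed(traj)
    class(traj) <- c("trajectory", "data.frame")
    attr(traj, "chamber") <- c(x = lx, y = ly)
    traj
  })
}

# Fold an unbounded coordinate into [0, L] by reflection at the walls.
reflect_fold <- function(p, L) {
  L - abs(L - (p %% (2 * L)))
}

# Per-frame speed from forward differences; last frame repeats.
frame_speed <- function(traj) {
  n <- nrow(traj)
  if (n < 2L) return(rep(0, n))
  d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2) / diff(traj$t)
  c(d, d[n - 1L])
}

# Evaluate an expression with a temporary RNG seed, restoring global state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate one cell's activity train along a trajectory
#'
#' Inhomogeneous Poisson events on the frame grid. The intensity at
#' position p is `baseline + peak * exp(-d^2 / (2 sigma^2))`, where d is the
#' distance from p to the cell's field center rotated by the trial's
#' ensemble orientation about the chamber center (plus the feature-sensitive
#' context offset in context B), all scaled by the day's across-context rate
#' gain. Event weights are per-frame Poisson counts (so they emulate
#' deconvolved event weights as well as spike counts) and events occur only
#' at sampled timestamps.
#'
#' @param trajectory Output of [simulate_trajectory()].
#' @param cell_spec List with `center_x`, `center_y` (cm), `class`
#'   ("FI"/"FS"), and optionally `peak_rate_hz`, `noise_rate_hz`,
#'   `sigma_cm` overriding the config.
#' @param trial_context "A" or "B".
#' @param ensemble_orientation Trial ensemble orientation in degrees; the
#'   cell's applied rotation must lie in {0, 180} (geometric axis).
#' @param config A [sim_config()].
#' @param seed Integer stream seed.
#' @param rate_gain Across-context gain applied in context B (default 1).
#' @return An `activity_train`: data.frame with `t` (s) and `w`
#'   (positive integer weights).
#' @export
simulate_activity <- function(trajectory, cell_spec, trial_context,
                              ensemble_orientation, config, seed,
                              rate_gain = 1) {
  if (!ensemble_orientation %in% c(0, 180)) {
    stop("ensemble_orientation must be 0 or 180", call. = FALSE)
  }
  if (!trial_context %in% c("A", "B")) {
    stop("trial_context must be 'A' or 'B'", call. = FALSE)
  }
  sigma <- cell_spec$sigma_cm %||% config$field_sigma_cm
  peak <- cell_spec$peak_rate_hz %||% config$peak_rate_hz
  base <- cell_spec$noise_rate_hz %||% config$noise_rate_hz

  rot <- ensemble_orientation
  if (identical(cell_spec$class, "FS") && trial_context == "B") {
    rot <- (rot + config$fs_context_offset_deg) %% 360
  }
  ctr <- rotate_point(cell_spec$center_x, cell_spec$center_y, rot,
                      config$chamber_x_cm / 2, config$chamber_y_cm / 2)
  gain <- if (trial_context == "B") rate_gain else 1

  d2 <- (trajectory$x - ctr[1])^2 + (trajectory$y - ctr[2])^2
  lambda <- gain * (base + peak * exp(-d2 / (2 * sigma^2)))
  dt <- if (nrow(trajectory) > 1L) diff(trajectory$t[1:2]) else 1

  withr_seed(seed, {
    counts <- stats::rpois(length(lambda), lambda * dt)
    keep <- counts > 0L
    train <- data.frame(t = trajectory$t[keep], w = counts[keep])
    class(train) <- c("activity_train", "data.frame")
    train
  })
}

# Rotate (x, y) about (cx, cy) by a quarter-turn multiple in degrees.
rotate_point <- function(x, y, deg, cx, cy) {
  th <- deg * pi / 180
  dx <- x - cx; dy <- y - cy
  c(cx + cos(th) * dx - sin(th) * dy,
    cy + sin(th) * dx + cos(th) * dy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full synthetic study with ground truth
#'
#' Produces one session bundle per animal per day. Each bundle holds per-trial
#' trajectories and per-cell activity trains, trial metadata (context,
#' ensemble orientation, dig sequence, reward corner), and complete ground
#' truth: per-day cell classes, field centers, per-trial ensemble
#' orientations and per-cell applied rotations, and the cross-day identity
#' map (cell ids persist across days).
#'
#' The first-dig corner is drawn from the day's categorical weights over
#' C/G/N/F; when the draw lands on the rewarded axis, the C-vs-G choice
#' matches the trial's ensemble orientation (0 deg -> C, 180 deg -> G)
#' with probability `p_dig_follows_orientation` and takes the opposite
#' corner otherwise, so 0.5 decouples dig labels from the ensemble
#' entirely. Feature-sensitive identity is carried
#' across days with probability `fs_identity_retention`; a dropped FS slot is
#' refilled from the FI pool so the FS fraction stays constant, emulating
#' dynamic FS ensembles. FI identities persist.
#'
#' @param config A [sim_config()].
#' @return A list of class `study`: `config`, plus `animals`, a list whose
#'   element `[[a]][[d]]` is the `session_bundle` for animal a on day d.
#' @examples
#' cfg <- sim_config(n_animals = 1, n_days = 1, trial_duration_s = 10,
#'                   n_fi_cells = 3, n_fs_cells = 1)
#' study <- generate_study(cfg)
#' study$animals[[1]][[1]]$trials
#' @export
generate_study <- function(config) {
  validate_sim_config(config)
  n_cells <- config$n_fi_cells + config$n_fs_cells
  animals <- vector("list", config$n_animals)

  for (a in seq_len(config$n_animals)) {
    cell_seed <- sub_seed(config$seed, a, 0L, 0L, 1L)
    cells <- withr_seed(cell_seed, {
      # rejection-sample eccentric field centers: disoriented mice sample
      # chamber edges, and a field at the rotation center would make the
      # cell's orientation (and any context offset) unidentifiable
      min_ecc <- 0.3 * config$chamber_x_cm
      cx <- numeric(n_cells); cy <- numeric(n_cells)
      for (i in seq_len(n_cells)) {
        repeat {
          px <- stats::runif(1, 0.15 * config$chamber_x_cm,
                             0.85 * config$chamber_x_cm)
          py <- stats::runif(1, 0.15 * config$chamber_y_cm,
                             0.85 * config$chamber_y_cm)
          d <- sqrt((px - config$chamber_x_cm / 2)^2 +
                      (py - config$chamber_y_cm / 2)^2)
          if (d >= min_ecc) break
        }
        cx[i] <- px; cy[i] <- py
      }
      data.frame(
        cell_id = sprintf("a%02d_c%03d", a, seq_len(n_cells)),
        center_x = cx, center_y = cy,
        stringsAsFactors = FALSE
      )
    })
    class_now <- rep(c("FI", "FS"),
                     c(config$n_fi_cells, config$n_fs_cells))
    days <- vector("list", config$n_days)
    for (d in seq_len(config$n_days)) {
      if (d > 1L) {
        class_now <- withr_seed(sub_seed(config$seed, a, d, 0L, 2L),
                                evolve_fs_identity(class_now,
                                                   config$fs_identity_retention))
      }
      days[[d]] <- simulate_session(config, a, d, cells, class_now)
    }
    animals[[a]] <- days
  }
  structure(list(config = config, animals = animals), class = "study")
}

# Carry FS identity to the next day; dropped FS slots are refilled from the
# FI pool so the FS count is conserved.
evolve_fs_identity <- function(class_prev, retention) {
  cls <- class_prev
  fs_idx <- which(class_prev == "FS")
  kept <- stats::runif(length(fs_idx)) < retention
  cls[fs_idx[!kept]] <- "FI"
  n_drop <- sum(!kept)
  if (n_drop > 0L) {
    pool <- which(cls == "FI" & class_prev == "FI")
    promote <- pool[sample.int(length(pool), min(n_drop, length(pool)))]
    cls[promote] <- "FS"
  }
  cls
}

simulate_session <- function(config, animal, day, cells, cell_class) {
  nt <- config$trials_per_day
  n_cells <- nrow(cells)
  gain <- config$rate_gain_by_day[day]
  coher <- config$coherence_by_day[day]
  dig_p <- config$dig_probs_by_day[day, ]

  context <- rep(c("A", "B"), length.out = nt)
  meta_seed <- sub_seed(config$seed, animal, day, 0L, 3L)
  trials <- withr_seed(meta_seed, {
    orientation <- sample(c(0, 180), nt, replace = TRUE)
    dig1 <- character(nt)
    dig2 <- character(nt)
    for (i in seq_len(nt)) {
      corner <- sample(c("C", "G", "N", "F"), 1L, prob = dig_p)
      if (corner %in% c("C", "G")) {
        # rewarded-axis digs match the ensemble orientation (0 -> C,
        # 180 -> G) with probability p, otherwise the opposite corner:
        # p = 1 is deterministic coupling, p = 0.5 full independence
        match_corner <- if (orientation[i] == 0) "C" else "G"
        corner <- if (stats::runif(1) <
                      config$p_dig_follows_orientation) {
          match_corner
        } else {
          setdiff(c("C", "G"), match_corner)
        }
      }
      dig1[i] <- corner
      dig2[i] <- if (corner == "C") NA_character_ else {
        if (stats::runif(1) < 0.6) "C" else {
          sample(setdiff(c("C", "G", "N", "F"), corner), 1L)
        }
      }
    }
    data.frame(
      trial_id = sprintf("a%02d_d%d_t%02d", animal, day, seq_len(nt)),
      day = day, context = context,
      orientation_deg = orientation,
      chamber_orientation_deg = 90 * ((seq_len(nt) - 1L) %% 4L),
      dig1 = dig1, dig2 = dig2,
      reward_corner = ifelse(context == "A", 1L, 2L),
      stringsAsFactors = FALSE
    )
  })

  # per-cell applied rotation: follow the ensemble or flip to the
  # opposite geometric orientation
  rot_seed <- sub_seed(config$seed, animal, day, 0L, 4L)
  applied_rot <- withr_seed(rot_seed, {
    follow <- matrix(stats::runif(n_cells * nt) < coher, n_cells, nt)
    base <- matrix(rep(trials$orientation_deg, each = n_cells), n_cells, nt)
    rot <- ifelse(follow, base, (base + 180) %% 360)
    dimnames(rot) <- list(cells$cell_id, trials$trial_id)
    rot
  })

  trajectories <- vector("list", nt)
  activity <- vector("list", nt)
  names(trajectories) <- names(activity) <- trials$trial_id
  for (i in seq_len(nt)) {
    trajectories[[i]] <- simulate_trajectory(
      config, sub_seed(config$seed, animal, day, i, 5L))
    acts <- vector("list", n_cells)
    names(acts) <- cells$cell_id
    for (j in seq_len(n_cells)) {
      spec <- list(center_x = cells$center_x[j],
                   center_y = cells$center_y[j],
                   class = cell_class[j])
      acts[[j]] <- simulate_activity(
        trajectories[[i]], spec, trials$context[i],
        applied_rot[j, i], config,
        seed = sub_seed(config$seed, animal, day, i, 6L + j),
        rate_gain = gain)
    }
    activity[[i]] <- acts
  }

  cells_day <- cells
  cells_day$class <- cell_class
  structure(list(
    animal = animal, day = day,
    trials = trials,
    trajectories = trajectories,
    activity = activity,
    cells = cells_day,
    ground_truth = list(
      ensemble_orientation = stats::setNames(trials$orientation_deg,
                                             trials$trial_id),
      applied_rotation = applied_rot,
      cell_class = stats::setNames(cell_class, cells$cell_id),
      rate_gain = gain, coherence = coher
    )
  ), class = "session_bundle")
}
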