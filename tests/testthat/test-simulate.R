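test_that("trajectories stay inside the chamber with the right sample count", {
  cfg <- sim_config(trial_duration_s = 60, frame_rate_hz = 30)
  tr <- simulate_trajectory(cfg, trial_seed = 7)
  expect_equal(nrow(tr), 1800)
  expect_true(all(diff(tr$t) > 0))
  expect_true(all(tr$x >= 0 & tr$x <= 20))
  expect_true(all(tr$y >= 0 & tr$y <= 30))
  # slow epochs exist so the 2 cm/s filter bites, but most time is moving
  expect_gt(mean(tr$speed <= 2), 0)
  expect_gt(mean(tr$speed > 2), 0.5)
})

test_that("zero-velocity parameters give a stationary animal", {
  cfg <- sim_config(trial_duration_s = 10)
  tr <- simulate_trajectory(cfg, trial_seed = 1, speed_sd_cm_s = 0)
  expect_equal(length(unique(tr$x)), 1L)
  expect_equal(length(unique(tr$y)), 1L)
  expect_true(all(tr$speed == 0))
})

test_that("simulation streams are deterministic and bit-identical", {
  cfg <- quick_config(n_fi_cells = 2, n_fs_cells = 1,
                      trial_duration_s = 10, seed = 5)
  expect_identical(simulate_trajectory(cfg, 3), simulate_trajectory(cfg, 3))
  expect_identical(generate_study(cfg), generate_study(cfg))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(trials_per_day = 11), "even")
  expect_error(sim_config(chamber_x_cm = 20, chamber_y_cm = 20), "2 : 3")
  expect_error(sim_config(trial_duration_s = 200), "180")
  expect_error(sim_config(p_dig_follows_orientation = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(dig_probs_by_day = matrix(0.3, 3, 4)), "summing")
})

test_that("activity is inhomogeneous Poisson with the stated mean", {
  cfg <- sim_config(trial_duration_s = 100, frame_rate_hz = 20,
                    noise_rate_hz = 5, peak_rate_hz = 0)
  tr <- simulate_trajectory(cfg, 1)
  spec <- list(center_x = 10, center_y = 15, class = "FI")
  counts <- vapply(1:20, function(s) {
    sum(simulate_activity(tr, spec, "A", 0, cfg, seed = s)$w)
  }, numeric(1))
  # constant 5 Hz over 100 s: mean count 500, se of the mean over 20 reps
  expect_lt(abs(mean(counts) - 500), 3 * sqrt(500 / 20))

  # zero intensity -> empty train
  cfg0 <- sim_config(noise_rate_hz = 0, peak_rate_hz = 0)
  expect_equal(nrow(simulate_activity(tr, spec, "A", 0, cfg0, seed = 1)), 0L)
})

test_that("orientation 180 reflects the expected event mass about the center", {
  cfg <- sim_config(trial_duration_s = 120, frame_rate_hz = 20,
                    noise_rate_hz = 0, peak_rate_hz = 40,
                    field_sigma_cm = 3)
  tr <- simulate_trajectory(cfg, 2)
  spec <- list(center_x = 5, center_y = 8, class = "FI")
  pos_of <- function(orient) {
    ev <- simulate_activity(tr, spec, "A", orient, cfg, seed = 9)
    idx <- reorientr:::event_frames(ev$t, tr$t)
    c(weighted.mean(tr$x[idx], ev$w), weighted.mean(tr$y[idx], ev$w))
  }
  p0 <- pos_of(0)
  p180 <- pos_of(180)
  # centrally symmetric: p180 ~ (20, 30) - p0
  expect_lt(max(abs(p180 - (c(20, 30) - p0))), 2.5)
  expect_error(simulate_activity(tr, spec, "A", 90, cfg, seed = 1),
               "0 or 180")
})

test_that("dig outcomes follow the day's categorical weights", {
  cfg <- sim_config(n_animals = 20, n_days = 1, n_fi_cells = 0,
                    n_fs_cells = 0, trial_duration_s = 1, seed = 8)
  study <- generate_study(cfg)
  digs <- unlist(lapply(study$animals, function(a) a[[1]]$trials$dig1))
  share_cg <- mean(digs %in% c("C", "G"))
  # day-1 weights put 75% of first digs on the rewarded axis
  expect_lt(abs(share_cg - 0.75), 3 * sqrt(0.75 * 0.25 / length(digs)))
})

test_that("perfect orientation coupling makes dig labels match orientation", {
  cfg <- sim_config(n_animals = 4, n_days = 1, n_fi_cells = 0,
                    n_fs_cells = 0, trial_duration_s = 1,
                    p_dig_follows_orientation = 1, seed = 3)
  study <- generate_study(cfg)
  for (a in study$animals) {
    tr <- a[[1]]$trials
    cg <- tr$dig1 %in% c("C", "G")
    expect_true(all(tr$dig1[cg] == ifelse(tr$orientation_deg[cg] == 0,
                                          "C", "G")))
  }
})

test_that("FS identity retention 1 keeps every FS cell FS on all days", {
  cfg <- sim_config(n_animals = 2, n_days = 3, n_fi_cells = 3,
                    n_fs_cells = 2, trial_duration_s = 2,
                    fs_identity_retention = 1, seed = 4)
  study <- generate_study(cfg)
  for (a in study$animals) {
    classes <- vapply(a, function(b) b$ground_truth$cell_class,
                      character(5))
    expect_true(all(apply(classes, 1, function(r) length(unique(r)) == 1)))
    expect_equal(sum(classes[, 1] == "FS"), 2L)
  }
})

test_that("session bundles round-trip through CSV/JSON", {
  cfg <- quick_config(n_fi_cells = 2, n_fs_cells = 1,
                      trial_duration_s = 5, seed = 6)
  b <- generate_study(cfg)$animals[[1]][[1]]
  dir <- withr::local_tempdir()
  write_session_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("trajectories.csv", "events.csv", "trials.csv", "cells.csv",
      "ground_truth.json")))))
  b2 <- read_session_bundle(dir)
  expect_equal(b2$trials, b$trials)
  expect_equal(b2$ground_truth$applied_rotation,
               b$ground_truth$applied_rotation)
  expect_equal(b2$activity[[3]][[2]]$t, b$activity[[3]][[2]]$t)
  expect_equal(b2$trajectories[[1]]$x, b$trajectories[[1]]$x)
})
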