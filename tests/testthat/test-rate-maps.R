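test_that("position alignment recovers canonical coordinates exactly", {
  canon <- rbind(c(0, 0), c(20, 0), c(20, 30), c(0, 30))
  pts <- cbind(runif(50, 0, 20), runif(50, 0, 30))
  out <- align_positions(pts, canon, 0)
  expect_lt(max(abs(out - pts)), 1e-9)

  # chamber rotated 90 deg in the video frame
  rot90 <- function(p) cbind(-p[, 2], p[, 1])
  out <- align_positions(rot90(pts), rot90(canon)[c(2, 3, 4, 1), ],
                         trial_orientation = 90)
  expect_lt(max(abs(out - pts)), 1e-9)
})

test_that("a synthetic homography round-trips below 1e-6 cm", {
  H <- matrix(c(1.2, 0.1, 5,
                -0.05, 0.9, -3,
                1e-3, -5e-4, 1), 3, 3, byrow = TRUE)
  canon <- rbind(c(0, 0), c(20, 0), c(20, 30), c(0, 30))
  corners_video <- reorientr:::apply_homography(solve(H), canon)
  pts <- cbind(runif(200, 0, 20), runif(200, 0, 30))
  video <- reorientr:::apply_homography(solve(H), pts)
  out <- align_positions(video, corners_video, 0)
  expect_lt(max(abs(out - pts)), 1e-6)

  expect_error(align_positions(pts, rbind(c(0, 0), c(1, 1), c(2, 2),
                                          c(3, 3))),
               "degenerate")
})

test_that("rate is activity over occupancy at the pixel level", {
  # 2 s spent oscillating inside one pixel; one unit event; no smoothing
  x <- rep(c(10.2, 10.8), 10)
  tr <- toy_trajectory(x, rep(20.5, 20), dt = 0.1)
  map <- compute_rate_map(tr, toy_train(0.5), sigma_cm = 0,
                          occupancy_min = 0.01)
  expect_equal(map$rate[11, 21], 0.5)
  expect_equal(sum(map$mask), 1L)

  # no events -> all-zero rates on sampled pixels
  map0 <- compute_rate_map(tr, toy_train(numeric(0)), sigma_cm = 0,
                           occupancy_min = 0.01)
  expect_true(all(map0$rate[map0$mask] == 0))
})

test_that("homogeneous Poisson activity recovers its rate on the map", {
  cfg <- sim_config(trial_duration_s = 120, frame_rate_hz = 20,
                    noise_rate_hz = 5, peak_rate_hz = 0)
  means <- vapply(1:5, function(s) {
    tr <- simulate_trajectory(cfg, s)
    ev <- simulate_activity(tr, list(center_x = 1, center_y = 1,
                                     class = "FI"), "A", 0, cfg, seed = s)
    m <- compute_rate_map(tr, ev)
    # occupancy-weighted mean rate equals the homogeneous intensity
    sum(m$rate[m$mask] * m$occupancy[m$mask]) / sum(m$occupancy[m$mask])
  }, numeric(1))
  expect_lt(abs(mean(means) - 5), 3 * sqrt(5 / (100 * 5)) * 5)
})

test_that("speed filter and occupancy mask behave as specified", {
  # all samples below the speed cutoff -> empty-map flag, no NaNs leak
  tr <- toy_trajectory(rep(10, 50), rep(10, 50))
  map <- compute_rate_map(tr, toy_train(1))
  expect_true(map$empty)
  expect_true(all(!map$mask))
  expect_true(all(is.na(map$rate)))

  # unvisited chamber regions are masked out
  x <- rep(c(3.2, 3.8), 40)
  tr <- toy_trajectory(x, rep(c(5.2, 5.8), 40), dt = 0.1)
  map <- compute_rate_map(tr, NULL, sigma_cm = 3)
  expect_false(map$mask[18, 28])
  expect_true(any(map$mask))
})

test_that("square compression re-bins raw data and conserves event weight", {
  cfg <- sim_config(trial_duration_s = 30, frame_rate_hz = 20)
  tr <- simulate_trajectory(cfg, 4)
  ev <- simulate_activity(tr, list(center_x = 6, center_y = 20,
                                   class = "FI"), "A", 0, cfg, seed = 2)
  sq <- compress_to_square(tr, ev)
  expect_equal(dim(sq$rate), c(20L, 20L))
  rect <- compute_rate_map(tr, ev)
  # total binned event weight identical before normalisation
  expect_equal(sum(sq$activity_raw), sum(rect$activity_raw))

  # a single event maps to bin (floor(x/1), floor(y/1.5))
  x <- rep(c(7.1, 7.9), 30)
  tr1 <- toy_trajectory(x, rep(26.0, 60), dt = 0.1)
  sq1 <- compress_to_square(tr1, toy_train(1.0), sigma_cm = 0,
                            occupancy_min = 0.01)
  expect_true(sq1$activity_raw[8, 18] > 0)  # x in [7,8), y in [25.5,27)
  expect_equal(sum(sq1$activity_raw), 1)
})

test_that("smoothing is linear in the activity train", {
  cfg <- sim_config(trial_duration_s = 30, frame_rate_hz = 20)
  tr <- simulate_trajectory(cfg, 9)
  spec <- list(center_x = 14, center_y = 8, class = "FI")
  e1 <- simulate_activity(tr, spec, "A", 0, cfg, seed = 1)
  e2 <- simulate_activity(tr, spec, "A", 180, cfg, seed = 2)
  both <- toy_train(c(e1$t, e2$t), c(e1$w, e2$w))
  occ <- reorientr:::trial_occupancy(tr)
  m1 <- reorientr:::cell_rate_map(occ, e1)
  m2 <- reorientr:::cell_rate_map(occ, e2)
  m12 <- reorientr:::cell_rate_map(occ, both)
  sm <- function(a) occ$sx %*% a %*% t(occ$sy)
  expect_equal(sm(m12$activity_raw), sm(m1$activity_raw) +
                 sm(m2$activity_raw), tolerance = 1e-12)
})

test_that("trial rate statistics match their definitions", {
  x <- rep(c(10.2, 10.8), 25)
  tr <- toy_trajectory(x, rep(20.5, 50), dt = 0.1)  # 5 s filtered
  expect_equal(trial_rate_stats(toy_train(seq(0.1, 1, 0.1)), tr, "mean"), 2)
  expect_equal(trial_rate_stats(toy_train(numeric(0)), tr, "mean"), 0)

  still <- toy_trajectory(rep(1, 10), rep(1, 10))
  out <- trial_rate_stats(toy_train(0.5), still, "mean")
  expect_true(is.na(out) && isTRUE(attr(out, "undefined")))

  cfg <- sim_config(trial_duration_s = 30, frame_rate_hz = 20)
  tr2 <- simulate_trajectory(cfg, 3)
  ev <- simulate_activity(tr2, list(center_x = 5, center_y = 22,
                                    class = "FI"), "A", 0, cfg, seed = 7)
  map <- compute_rate_map(tr2, ev)
  peak <- trial_rate_stats(ev, tr2, "peak", map = map)
  wmean <- sum(map$rate[map$mask] * map$occupancy[map$mask]) /
    sum(map$occupancy[map$mask])
  expect_gte(peak, wmean)
})

test_that("spatial information follows the Skaggs formula", {
  # uniform map carries no information
  expect_equal(spatial_information(toy_map(matrix(3, 4, 4))), 0)
  # all activity in 1 of 4 equally occupied pixels -> log2(4) bits
  m <- toy_map(matrix(c(8, 0, 0, 0), 2, 2))
  expect_equal(spatial_information(m), 2)
  # 3-pixel toy, p = (.5, .25, .25), rates (2, 1, 0)
  m3 <- toy_map(matrix(c(2, 1, 0), 1, 3),
                occupancy = matrix(c(2, 1, 1), 1, 3))
  lam <- 0.5 * 2 + 0.25 * 1
  expected <- 0.5 * (2 / lam) * log2(2 / lam) +
    0.25 * (1 / lam) * log2(1 / lam)
  expect_equal(spatial_information(m3), expected)
  expect_equal(expected, 0.4780719, tolerance = 1e-6)
  # zero-rate map is undefined
  z <- spatial_information(toy_map(matrix(0, 2, 2)))
  expect_true(is.na(z) && isTRUE(attr(z, "undefined")))
})
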