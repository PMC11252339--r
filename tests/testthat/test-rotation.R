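# Independent enumeration oracle: Pearson correlation after explicit
# coordinate rotation of map A by k quarter-turns about the grid center.
oracle_rotation_corrs <- function(a, b) {
  n <- nrow(a)
  vapply(0:3, function(k) {
    ra <- matrix(NA_real_, n, n)
    for (i in 1:n) {
      for (j in 1:n) {
        ij <- c(i, j)
        for (q in seq_len(k)) ij <- c(n + 1 - ij[2], ij[1])
        ra[ij[1], ij[2]] <- a[i, j]
      }
    }
    stats::cor(as.numeric(ra), as.numeric(b))
  }, numeric(1))
}

test_that("best match rotation of a map with itself is 0 at r = 1", {
  set.seed(2)
  m <- toy_map(matrix(runif(400), 20, 20))
  rec <- best_match_rotation(m, m)
  expect_equal(rec$best_angle, 0)
  expect_equal(rec$best_correlation, 1)
})

test_that("a constructed 180-degree image is recovered exactly", {
  set.seed(3)
  a <- matrix(runif(400), 20, 20)
  b <- a[20:1, 20:1]
  rec <- best_match_rotation(toy_map(a), toy_map(b))
  expect_equal(rec$best_angle, 180)
  expect_equal(rec$best_correlation, 1, tolerance = 1e-12)
})

test_that("per-angle correlations match the enumeration oracle", {
  set.seed(4)
  for (rep in 1:5) {
    a <- matrix(runif(16), 4, 4)
    b <- matrix(runif(16), 4, 4)
    rec <- best_match_rotation(toy_map(a), toy_map(b), min_overlap = 4)
    expect_equal(unname(rec$correlations), oracle_rotation_corrs(a, b),
                 tolerance = 1e-12)
  }
})

test_that("rotation symmetry: swapping maps mirrors the best angle", {
  set.seed(5)
  for (rep in 1:5) {
    a <- toy_map(matrix(runif(400), 20, 20))
    b <- toy_map(matrix(runif(400), 20, 20))
    ab <- best_match_rotation(a, b)
    ba <- best_match_rotation(b, a)
    expect_equal(ba$best_angle, (360 - ab$best_angle) %% 360)
    expect_equal(ba$best_correlation, ab$best_correlation,
                 tolerance = 1e-12)
  }
})

test_that("ties break to the smallest angle and thin overlap is undefined", {
  # 4-fold rotationally symmetric map: all four correlations equal
  xs <- (1:20) - 10.5
  sym <- outer(xs, xs, function(x, y) exp(-(x^2 + y^2) / 20))
  rec <- best_match_rotation(toy_map(sym), toy_map(sym))
  expect_equal(rec$best_angle, 0)

  # joint overlap below threshold at every rotation
  mask <- matrix(FALSE, 20, 20); mask[1:3, 1:3] <- TRUE
  a <- toy_map(matrix(runif(400), 20, 20), mask = mask)
  rec <- best_match_rotation(a, a, min_overlap = 20)
  expect_true(rec$undefined)

  # zero-variance map has no defined correlation
  flat <- toy_map(matrix(1, 20, 20))
  expect_true(best_match_rotation(flat, flat)$undefined)
})

test_that("BMR proportions aggregate per cell then per animal", {
  rec <- data.frame(
    cell_id = rep(c("c1", "c2"), each = 3),
    trial_i = "a", trial_j = "b",
    best_angle = c(0, 0, 0, 0, 180, 180),
    defined = TRUE, active_both = TRUE)
  pr <- bmr_proportions(rec)
  expect_equal(pr$per_cell$p0, c(1, 1 / 3))
  expect_equal(unname(pr$animal),
               c(mean(c(1, 1 / 3)), 0, mean(c(0, 2 / 3)), 0))
  expect_equal(sum(pr$animal), 1)

  # undefined-only cells are excluded and reported
  rec$defined[4:6] <- FALSE
  pr <- bmr_proportions(rec)
  expect_equal(pr$excluded_cells, "c2")
})

test_that("a 12-trial session yields 66 pairwise comparisons per cell", {
  sq <- shared_square_maps()
  rec <- session_bmr(sq)
  counts <- table(rec$cell_id)
  expect_true(all(counts == choose(12, 2)))
  expect_equal(unname(counts[1]), 66L)
})

test_that("center-out differences wrap correctly and detect bimodality", {
  ang <- matrix(rep(40, 6), 1, dimnames = list("c1", NULL))
  d <- center_out_differences(ang)
  expect_true(all(d$pooled == 0))

  ang <- matrix(rep(c(10, 190), 3), 1, dimnames = list("c1", NULL))
  d <- center_out_differences(ang)
  expect_true(all(d$pooled %in% c(0, 180)))

  # a cell with fewer than two defined angles is skipped
  ang <- rbind(c1 = c(10, NA, NA), c2 = c(10, 50, NA))
  d <- center_out_differences(ang)
  expect_equal(d$skipped_cells, "c1")

  # differences of iid uniform angles are uniform on [0, 360): one
  # independent difference per cell (2 trials each)
  set.seed(11)
  ang <- matrix(runif(2e4, 0, 360), ncol = 2,
                dimnames = list(sprintf("c%05d", 1:1e4), NULL))
  d <- center_out_differences(ang)
  ks <- stats::ks.test(d$pooled / 360, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("angle doubling collapses axial pairs and measures concentration", {
  d <- double_angles(c(10, 190))
  expect_equal(d$doubled, c(20, 20))
  expect_equal(d$r_bar, 1)

  d <- double_angles(c(0, 90, 180, 270))
  expect_equal(d$doubled, c(0, 180, 0, 180))
  expect_equal(d$r_bar, 0, tolerance = 1e-12)

  set.seed(12)
  d <- double_angles(runif(5000, 0, 360))
  expect_lt(d$r_bar, 0.05)
})

test_that("coherency shares rank correctly and sit at 25% under randomness", {
  mk_rec <- function(angles) {
    data.frame(cell_id = sprintf("c%d", seq_along(angles)),
               trial_i = "t1", trial_j = "t2", best_angle = angles,
               defined = TRUE, active_both = TRUE)
  }
  trials <- data.frame(trial_id = c("t1", "t2"), context = c("A", "B"))
  tab <- session_coherency(mk_rec(rep(180, 8)), trials)
  expect_equal(tab$rank1, 1)
  expect_equal(tab$angle1, 180)
  expect_equal(tab$rank2 + tab$rank3 + tab$rank4, 0)
  expect_equal(tab$comparison, "across")

  tab <- session_coherency(mk_rec(c(rep(0, 10), rep(90, 6), rep(180, 3),
                                    270)), trials)
  expect_equal(c(tab$rank1, tab$rank2, tab$rank3, tab$rank4),
               c(0.5, 0.3, 0.15, 0.05))
  expect_true(all(diff(c(tab$rank1, tab$rank2, tab$rank3, tab$rank4)) <= 0))
  expect_equal(tab$rank1 + tab$rank2 + tab$rank3 + tab$rank4, 1)

  # independent uniform BMRs: every expected share is chance (25%)
  set.seed(13)
  shares <- replicate(300, {
    tab <- session_coherency(mk_rec(sample(c(0, 90, 180, 270), 12,
                                           replace = TRUE)), trials)
    c(tab$s0, tab$s90, tab$s180, tab$s270)
  })
  expect_lt(max(abs(rowMeans(shares) - 0.25)), 0.02)

  # pairs with no included cells are dropped with a log entry
  r <- mk_rec(c(0, 90)); r$active_both <- FALSE
  tab <- session_coherency(r, trials)
  expect_equal(nrow(tab), 0L)
  expect_length(attr(tab, "dropped_pairs"), 1L)
})

test_that("joint BMR distributions concentrate where constructed", {
  tab <- data.frame(angle1 = rep(180, 5), angle2 = rep(0, 5))
  j <- joint_bmr_distribution(tab)
  expect_equal(j$joint["180", "0"], 1)
  expect_equal(sum(j$joint), 1)
  expect_equal(unname(j$marginal_first["180"]), 1)

  # per-animal averaging weights animals equally
  tab <- data.frame(angle1 = c(0, 0, 180), angle2 = c(90, 90, 0),
                    animal = c(1, 1, 2))
  j <- joint_bmr_distribution(tab)
  expect_equal(j$joint["0", "90"], 0.5)
  expect_equal(j$joint["180", "0"], 0.5)
})
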