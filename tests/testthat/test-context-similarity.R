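# Enumeration oracle for within-context alignment: try every 0/180
# assignment explicitly and score mean pairwise correlation.
oracle_alignment <- function(rates) {
  k <- length(rates)
  combos <- expand.grid(rep(list(c(0, 180)), k - 1))
  best <- NULL
  for (r in seq_len(nrow(combos))) {
    rot <- c(0, as.numeric(combos[r, ]))
    aligned <- lapply(seq_len(k), function(i) {
      if (rot[i] == 180) rates[[i]][nrow(rates[[i]]):1,
                                    ncol(rates[[i]]):1] else rates[[i]]
    })
    vals <- c()
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        vals <- c(vals, stats::cor(as.numeric(aligned[[i]]),
                                   as.numeric(aligned[[j]])))
      }
    }
    score <- mean(vals)
    if (is.null(best) || score > best$score + 1e-12) {
      best <- list(score = score, rot = rot)
    }
  }
  best
}

test_that("identical maps align at 0 with mean pairwise r of 1", {
  set.seed(21)
  m <- matrix(runif(400), 20, 20)
  al <- align_within_context(lapply(1:4, function(i) toy_map(m)))
  expect_equal(al$rotations, rep(0, 4))
  expect_equal(al$mean_pairwise_r, 1)
})

test_that("alternating 180-degree flips are recovered exactly", {
  set.seed(22)
  m <- matrix(runif(400), 20, 20)
  flipped <- m[20:1, 20:1]
  al <- align_within_context(list(toy_map(m), toy_map(flipped),
                                  toy_map(m), toy_map(flipped)))
  expect_equal(al$rotations, c(0, 180, 0, 180))
  expect_equal(al$mean_pairwise_r, 1, tolerance = 1e-12)
})

test_that("noisy planted orientations match the enumeration oracle", {
  set.seed(23)
  base <- matrix(runif(400), 20, 20)
  planted <- c(0, 180, 180, 0)
  rates <- lapply(planted, function(r) {
    noisy <- base + matrix(rnorm(400, 0, 0.3), 20, 20)
    if (r == 180) noisy[20:1, 20:1] else noisy
  })
  al <- align_within_context(lapply(rates, toy_map))
  orc <- oracle_alignment(rates)
  expect_equal(al$rotations, orc$rot)
  expect_equal(al$mean_pairwise_r, orc$score, tolerance = 1e-12)
})

test_that("context similarity absorbs geometric flips but not quarter-turn remaps", {
  set.seed(24)
  m <- matrix(runif(400), 20, 20)
  avg <- function(x) list(rate = x, mask = matrix(TRUE, 20, 20),
                          bin_x = 1, bin_y = 1)
  same <- context_similarity(avg(m), avg(m))
  expect_equal(same$value, 1)
  expect_equal(same$class, "FI")

  flip <- context_similarity(avg(m), avg(m[20:1, 20:1]))
  expect_equal(flip$value, 1, tolerance = 1e-12)
  expect_equal(flip$class, "FI")

  # quarter-turn remap: exact value from brute-force correlation
  q <- reorientr:::rot_quarter(m, 1)
  quarter <- context_similarity(avg(m), avg(q))
  expected <- max(stats::cor(as.numeric(m), as.numeric(q)),
                  stats::cor(as.numeric(m),
                             as.numeric(q[20:1, 20:1])))
  expect_equal(quarter$value, expected, tolerance = 1e-12)
  expect_lt(quarter$value, 0.3)
  expect_equal(quarter$class, "FS")
})

test_that("similarity is invariant to flipping all of one context's maps", {
  b <- shared_session()
  sq <- shared_square_maps()
  sc1 <- session_context_similarity(sq, b$trials)
  flipped <- lapply(names(sq), function(tid) {
    if (b$trials$context[b$trials$trial_id == tid] != "B") {
      return(sq[[tid]])
    }
    lapply(sq[[tid]], function(m) {
      m$rate <- reorientr:::rot_half(m$rate)
      m$mask <- reorientr:::rot_half(m$mask)
      m$activity_raw <- reorientr:::rot_half(m$activity_raw)
      m
    })
  })
  names(flipped) <- names(sq)
  sc2 <- session_context_similarity(flipped, b$trials)
  expect_equal(sc2$similarity, sc1$similarity, tolerance = 1e-10)
})

test_that("every score-defined cell is exactly one of FI or FS", {
  sc <- session_context_similarity(shared_square_maps(),
                                   shared_session()$trials)
  defined <- !is.na(sc$similarity)
  expect_true(all(sc$class[defined] %in% c("FI", "FS")))
  expect_true(all(sc$class[!defined] == "undefined"))
  expect_true(all((sc$similarity[defined] <= 0.3) ==
                    (sc$class[defined] == "FS")))
})

test_that("the known 180-degree edge case classifies as FI", {
  # a cell stable within each context whose maps all rotate 180 degrees
  # across contexts: across-context alignment absorbs the flip
  set.seed(25)
  m <- matrix(runif(400), 20, 20)
  ctx_A <- lapply(1:3, function(i) toy_map(m))
  ctx_B <- lapply(1:3, function(i) toy_map(m[20:1, 20:1]))
  al_A <- align_within_context(ctx_A)
  al_B <- align_within_context(ctx_B)
  cs <- context_similarity(al_A$average, al_B$average)
  expect_equal(cs$value, 1, tolerance = 1e-12)
  expect_equal(cs$class, "FI")
})

test_that("decile curve is perfect when within equals across", {
  set.seed(26)
  scores <- data.frame(cell_id = sprintf("c%03d", 1:60),
                       similarity = runif(60, -0.2, 0.9),
                       n_fields_A = 3L, n_fields_B = 3L)
  scores$within_avg <- scores$similarity
  dc <- within_across_decile_curve(scores)
  expect_equal(nrow(dc$curve), 10L)
  expect_true(all(abs(dc$curve$r - 1) < 1e-12))
  expect_equal(length(dc$boundaries), 11L)

  # deciles with fewer than 3 cells are flagged undefined
  small <- scores[1:20, ]
  dc2 <- within_across_decile_curve(small)
  expect_true(all(is.na(dc2$curve$r)))
  expect_true(all(dc2$curve$n == 2L))
})

test_that("decile membership respects the inclusion rule", {
  scores <- data.frame(cell_id = c("a", "b"), similarity = c(0.5, 0.4),
                       n_fields_A = c(3L, 1L), n_fields_B = c(3L, 3L),
                       within_avg = c(0.5, 0.4))
  expect_error(within_across_decile_curve(scores), "at least 10")
})

test_that("noiseless asymptotic data recover exact parameters", {
  x <- 1:10
  y <- 0.8 - (0.8 - (-0.4)) * exp(-0.7 * x)
  fit <- fit_asymptotic_regression(x, y)
  expect_true(fit$converged)
  expect_equal(fit$a, 0.8, tolerance = 1e-6)
  expect_equal(fit$b, -0.4, tolerance = 1e-6)
  expect_equal(fit$c, 0.7, tolerance = 1e-6)
  expect_equal(fit$half_life, log(2) / fit$c)
  expect_equal(fit$root, -log(0.8 / 1.2) / 0.7, tolerance = 1e-6)
  expect_equal(predict_asymptotic(fit, x), y, tolerance = 1e-8)
  expect_lt(fit$RSE, 1e-6)
})

test_that("degenerate series produce a fit-failure report, not a fallback", {
  expect_error(fit_asymptotic_regression(1:10, rep(0.5, 10)),
               "constant|degenerate")
  expect_error(fit_asymptotic_regression(1:3, c(0.1, 0.2, 0.3)),
               "at least 4")
})

test_that("threshold selection picks the decile containing the features", {
  x <- 1:10
  y <- 0.8 - 1.2 * exp(-0.9 * x)
  fit <- fit_asymptotic_regression(x, y)
  # half-life ln2/0.9 = 0.77 and root 0.45 both inside decile 1
  boundaries <- seq(-0.1, 0.8, by = 0.09)
  sel <- select_threshold(fit, boundaries)
  expect_equal(sel$decile, 1L)
  expect_equal(sel$threshold, boundaries[2])
  expect_true(sel$root_defined)
  expect_true(sel$unanimous)

  # no root when asymptote and intercept share a sign: flagged fallback
  y2 <- 0.8 - (0.8 - 0.2) * exp(-0.5 * x)
  fit2 <- fit_asymptotic_regression(x, y2)
  sel2 <- select_threshold(fit2, boundaries)
  expect_false(sel2$root_defined)
  expect_true(is.na(sel2$feature_deciles["root"]))
  # half-life ln2/0.5 = 1.39 -> decile 2; growth locus at the domain edge
  # -> decile 1; the lowest feature decile wins
  expect_equal(unname(sel2$feature_deciles["half_life"]), 2L)
  expect_equal(sel2$decile, 1L)
})
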