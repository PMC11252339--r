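#' Align a cell's trial maps within one context
#'
#' Disoriented animals produce maps that flip by 180 degrees between trials
#' along the rectangle's symmetry axis. This assigns each trial a rotation
#' in {0, 180} maximising the mean pairwise Pearson correlation among the
#' aligned maps, by exhaustive search over the 2^(k-1) assignments (the
#' first trial is fixed at 0; pairwise correlations depend only on relative
#' rotation).
#'
#' @param trial_maps Nonempty list of `rate_map` objects on a common grid.
#' @param min_overlap Minimum joint sampled pixels for a pairwise
#'   correlation to enter the objective.
#' @return List with `rotations` (numeric vector, 0/180 per trial),
#'   `average` (the pixelwise-mean aligned map; mask = sampled in >= 1
#'   aligned map, per-pixel trial counts in `count`) and
#'   `mean_pairwise_r`. For a single map the rotation is 0 and
#'   `mean_pairwise_r` is `NA`.
#' @export
align_within_context <- function(trial_maps, min_overlap = 20) {
  k <- length(trial_maps)
  stopifnot(k >= 1L)
  if (k == 1L) {
    return(list(rotations = 0,
                average = average_maps(trial_maps, 0),
                mean_pairwise_r = NA_real_))
  }
  c_same <- matrix(NA_real_, k, k)
  c_flip <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      c_same[i, j] <- masked_cor(trial_maps[[i]]$rate, trial_maps[[i]]$mask,
                                 trial_maps[[j]]$rate, trial_maps[[j]]$mask,
                                 min_overlap)
      c_flip[i, j] <- masked_cor(trial_maps[[i]]$rate, trial_maps[[i]]$mask,
                                 rot_half(trial_maps[[j]]$rate),
                                 rot_half(trial_maps[[j]]$mask),
                                 min_overlap)
    }
  }
  combos <- as.matrix(expand.grid(rep(list(c(0, 180)), k - 1L)))
  best_score <- -Inf
  best_rot <- rep(0, k)
  for (r in seq_len(nrow(combos))) {
    rot <- c(0, unname(combos[r, ]))
    vals <- c()
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        vals <- c(vals, if (rot[i] == rot[j]) c_same[i, j]
                        else c_flip[i, j])
      }
    }
    score <- mean(vals, na.rm = TRUE)
    if (is.finite(score) && score > best_score + 1e-12) {
      best_score <- score
      best_rot <- rot
    }
  }
  list(rotations = best_rot,
       average = average_maps(trial_maps, best_rot),
       mean_pairwise_r = if (is.finite(best_score)) best_score
                         else NA_real_)
}

# Pearson correlation over jointly sampled pixels; NA when overlap or
# variance is insufficient.
masked_cor <- function(ra, ma, rb, mb, min_overlap = 20) {
  joint <- ma & mb
  if (sum(joint) < min_overlap) return(NA_real_)
  va <- ra[joint]; vb <- rb[joint]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}

# 180-degree rotation of a (possibly rectangular) matrix.
rot_half <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]

# Pixelwise mean of maps after applying per-trial 0/180 rotations;
# mask-union with per-pixel counts.
average_maps <- function(trial_maps, rotations) {
  rotations <- rep_len(rotations, length(trial_maps))
  acc <- matrix(0, nrow(trial_maps[[1]]$rate), ncol(trial_maps[[1]]$rate))
  cnt <- matrix(0L, nrow(acc), ncol(acc))
  for (i in seq_along(trial_maps)) {
    r <- trial_maps[[i]]$rate
    m <- trial_maps[[i]]$mask
    if (rotations[i] == 180) {
      r <- rot_half(r); m <- rot_half(m)
    }
    r[!m] <- 0
    acc <- acc + r
    cnt <- cnt + m
  }
  rate <- acc / cnt
  rate[cnt == 0L] <- NA_real_
  list(rate = rate, mask = cnt > 0L, count = cnt,
       bin_x = trial_maps[[1]]$bin_x, bin_y = trial_maps[[1]]$bin_y)
}

#' Context similarity of a cell's average aligned maps
#'
#' The maximal Pearson correlation between the two contexts' average
#' aligned maps over {0, 180} rotation of the second, on jointly sampled
#' pixels. Cells at or below the threshold are feature-sensitive (FS,
#' location remapping across contexts); above it, feature-insensitive (FI).
#'
#' @param avg_A,avg_B Average aligned maps (as from
#'   [align_within_context()]`$average`).
#' @param threshold FS/FI classification boundary (default 0.3).
#' @param min_overlap Minimum joint sampled pixels.
#' @return List with `value`, `alignment` (the winning rotation of map B)
#'   and `class` ("FI", "FS", or "undefined" when no valid correlation
#'   exists).
#' @export
context_similarity <- function(avg_A, avg_B, threshold = 0.3,
                               min_overlap = 20) {
  r0 <- masked_cor(avg_A$rate, avg_A$mask, avg_B$rate, avg_B$mask,
                   min_overlap)
  r180 <- masked_cor(avg_A$rate, avg_A$mask, rot_half(avg_B$rate),
                     rot_half(avg_B$mask), min_overlap)
  if (is.na(r0) && is.na(r180)) {
    return(list(value = NA_real_, alignment = NA_real_,
                class = "undefined"))
  }
  vals <- c(`0` = r0, `180` = r180)
  best <- which.max(vals)  # ties resolve to 0
  list(value = vals[[best]], alignment = c(0, 180)[best],
       class = if (vals[[best]] <= threshold) "FS" else "FI")
}

#' Context similarity and FI/FS classification for a whole session
#'
#' For each cell: trials with a detected place field are collected per
#' context; maps are aligned within each context (0/180 exhaustive
#' search), averaged, the two averages aligned across contexts, and the
#' resulting correlation thresholded into FI/FS. The score is defined only
#' for cells with at least one field-bearing trial in each context.
#'
#' @param maps Output of [session_rate_maps()] (one grid for all trials).
#' @param trials Trial metadata (`trial_id`, `context`).
#' @param threshold FS/FI boundary.
#' @param min_overlap Minimum joint sampled pixels for correlations.
#' @return Data frame, one row per cell: `cell_id`, `similarity`,
#'   `alignment`, `class`, `n_fields_A`, `n_fields_B`, `within_A`,
#'   `within_B` (mean pairwise aligned correlation per context, `NA` with
#'   fewer than 2 field trials), `within_avg`.
#' @export
session_context_similarity <- function(maps, trials, threshold = 0.3,
                                       min_overlap = 20) {
  cell_ids <- names(maps[[1]])
  ctx <- stats::setNames(trials$context, trials$trial_id)
  rows <- lapply(cell_ids, function(cid) {
    has_field <- vapply(names(maps), function(tid) {
      length(detect_place_fields(maps[[tid]][[cid]])) > 0L
    }, logical(1))
    ids_A <- names(maps)[has_field & ctx[names(maps)] == "A"]
    ids_B <- names(maps)[has_field & ctx[names(maps)] == "B"]
    row <- data.frame(cell_id = cid, similarity = NA_real_,
                      alignment = NA_real_, class = "undefined",
                      n_fields_A = length(ids_A),
                      n_fields_B = length(ids_B),
                      within_A = NA_real_, within_B = NA_real_,
                      within_avg = NA_real_, stringsAsFactors = FALSE)
    if (length(ids_A) == 0L || length(ids_B) == 0L) return(row)
    al_A <- align_within_context(lapply(ids_A, function(t) maps[[t]][[cid]]),
                                 min_overlap)
    al_B <- align_within_context(lapply(ids_B, function(t) maps[[t]][[cid]]),
                                 min_overlap)
    cs <- context_similarity(al_A$average, al_B$average, threshold,
                             min_overlap)
    row$similarity <- cs$value
    row$alignment <- cs$alignment
    row$class <- cs$class
    row$within_A <- al_A$mean_pairwise_r
    row$within_B <- al_B$mean_pairwise_r
    w <- c(al_A$mean_pairwise_r, al_B$mean_pairwise_r)
    row$within_avg <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Within- vs across-context correlation per similarity decile
#'
#' Cells are split into deciles of the context-similarity distribution;
#' within each decile the Pearson R between member cells' average
#' within-context correlation and their across-context correlation (the
#' similarity value itself) is computed. Only cells with at least two
#' field-bearing trials per context (a defined within correlation) enter.
#' Deciles with fewer than 3 usable cells are flagged undefined.
#'
#' @param scores Data frame from [session_context_similarity()] (rows from
#'   several sessions may be concatenated).
#' @return List with `curve` (data frame: decile 1-10, n, r, lower,
#'   upper — the decile's empirical score boundaries) and `boundaries`
#'   (the 11 decile break points).
#' @export
within_across_decile_curve <- function(scores) {
  use <- scores[!is.na(scores$similarity) & !is.na(scores$within_avg) &
                  scores$n_fields_A >= 2L & scores$n_fields_B >= 2L, ,
                drop = FALSE]
  if (nrow(use) < 10L) {
    stop("need at least 10 cells with defined within and across correlations",
         call. = FALSE)
  }
  br <- stats::quantile(use$similarity, probs = seq(0, 1, 0.1), type = 7,
                        names = FALSE)
  dec <- pmin.int(pmax.int(findInterval(use$similarity, br,
                                        rightmost.closed = TRUE), 1L), 10L)
  curve <- do.call(rbind, lapply(1:10, function(d) {
    idx <- dec == d
    r <- if (sum(idx) >= 3L &&
             stats::sd(use$within_avg[idx]) > 0 &&
             stats::sd(use$similarity[idx]) > 0) {
      stats::cor(use$within_avg[idx], use$similarity[idx])
    } else NA_real_
    data.frame(decile = d, n = sum(idx), r = r,
               lower = br[d], upper = br[d + 1])
  }))
  list(curve = curve, boundaries = br)
}
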