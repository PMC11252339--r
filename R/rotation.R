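#' Best match rotation between two square maps
#'
#' Rotates map `a` by quarter turns (0, 90, 180, 270 degrees,
#' counter-clockwise, masks rotating with the data), computes the Pearson
#' correlation with the unrotated map `b` over pixels sampled in both, and
#' returns the rotation maximising it. Ties are broken by the smallest
#' angle. Rotations with joint overlap below `min_overlap` pixels, or with
#' zero variance on either side, are undefined.
#'
#' @param a,b `square_map` objects on the same grid.
#' @param min_overlap Minimum joint sampled-pixel count for a valid
#'   correlation.
#' @return A `bmr_record`: list with `best_angle`, `best_correlation`,
#'   `correlations` (named per angle, `NA` where undefined) and
#'   `undefined` (`TRUE` when no rotation admits a valid correlation).
#' @export
best_match_rotation <- function(a, b, min_overlap = 20) {
  stopifnot(inherits(a, "square_map"), inherits(b, "square_map"),
            all(dim(a$rate) == dim(b$rate)),
            nrow(a$rate) == ncol(a$rate))
  angles <- c(0, 90, 180, 270)
  rs <- vapply(0:3, function(k) {
    ra <- rot_quarter(a$rate, k)
    ma <- rot_quarter(a$mask, k)
    joint <- ma & b$mask
    if (sum(joint) < min_overlap) return(NA_real_)
    va <- ra[joint]; vb <- b$rate[joint]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
    stats::cor(va, vb)
  }, numeric(1))
  names(rs) <- angles
  if (all(is.na(rs))) {
    return(structure(list(best_angle = NA_real_,
                          best_correlation = NA_real_,
                          correlations = rs, undefined = TRUE),
                     class = "bmr_record"))
  }
  best <- which(rs == max(rs, na.rm = TRUE))[1L]  # smallest-angle tie rule
  structure(list(best_angle = angles[best], best_correlation = rs[[best]],
                 correlations = rs, undefined = FALSE),
            class = "bmr_record")
}

# Rotate a square matrix k quarter-turns counter-clockwise.
rot_quarter <- function(m, k) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

#' Best-match rotations for all trial pairs of a session
#'
#' @param square_maps Output of [session_rate_maps()] with `square = TRUE`.
#' @param min_overlap Passed to [best_match_rotation()].
#' @return Data frame with one row per (cell, trial pair i < j):
#'   `cell_id`, `trial_i`, `trial_j`, per-angle correlations `r0`...`r270`,
#'   `best_angle`, `best_correlation`, `defined`, and `active_both`
#'   (whether the cell carried any speed-filtered activity in both trials).
#' @export
session_bmr <- function(square_maps, min_overlap = 20) {
  trial_ids <- names(square_maps)
  cell_ids <- names(square_maps[[1]])
  nt <- length(trial_ids)
  active <- vapply(square_maps, function(tr) {
    vapply(tr, function(m) sum(m$activity_raw) > 0, logical(1))
  }, logical(length(cell_ids)))
  pairs <- utils::combn(nt, 2L)
  rows <- vector("list", ncol(pairs) * length(cell_ids))
  k <- 0L
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    for (c in seq_along(cell_ids)) {
      rec <- best_match_rotation(square_maps[[i]][[c]],
                                 square_maps[[j]][[c]], min_overlap)
      k <- k + 1L
      rows[[k]] <- data.frame(
        cell_id = cell_ids[c], trial_i = trial_ids[i],
        trial_j = trial_ids[j],
        r0 = rec$correlations[[1]], r90 = rec$correlations[[2]],
        r180 = rec$correlations[[3]], r270 = rec$correlations[[4]],
        best_angle = rec$best_angle,
        best_correlation = rec$best_correlation,
        defined = !rec$undefined,
        active_both = active[c, i] && active[c, j],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-cell and animal-level BMR proportions
#'
#' For each cell, the share of valid pairwise comparisons won by each
#' rotation; the animal-level distribution is the unweighted mean over its
#' cells. Cells without a single valid pair are excluded (and listed).
#'
#' @param records Data frame from [session_bmr()].
#' @return List with `per_cell` (data frame: cell_id, n_pairs, p0, p90,
#'   p180, p270), `animal` (named numeric summing to 1) and
#'   `excluded_cells`.
#' @export
bmr_proportions <- function(records) {
  angles <- c(0, 90, 180, 270)
  ok <- records[records$defined, , drop = FALSE]
  per <- do.call(rbind, lapply(split(ok, ok$cell_id), function(d) {
    pr <- as.numeric(table(factor(d$best_angle, levels = angles))) / nrow(d)
    data.frame(cell_id = d$cell_id[1], n_pairs = nrow(d),
               p0 = pr[1], p90 = pr[2], p180 = pr[3], p270 = pr[4],
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  excluded <- setdiff(unique(records$cell_id), per$cell_id)
  animal <- colMeans(per[, c("p0", "p90", "p180", "p270"), drop = FALSE])
  names(animal) <- angles
  list(per_cell = per, animal = animal, excluded_cells = excluded)
}

#' Circular pairwise differences of center-out angles
#'
#' For each cell with at least two defined trial angles, the difference
#' between every trial pair's angles wrapped to \[0, 360), plus a pooled
#' polar histogram.
#'
#' @param angles Matrix cells x trials of degrees (`NA` = undefined), as
#'   from [session_center_out_angles()].
#' @param bin_deg Histogram bin width in degrees.
#' @return List with `per_cell` (list of difference vectors), `pooled`
#'   (all differences), `histogram` (data frame: bin_start, count) and
#'   `skipped_cells`.
#' @export
center_out_differences <- function(angles, bin_deg = 20) {
  per <- list()
  skipped <- character()
  for (ci in seq_len(nrow(angles))) {
    a <- angles[ci, ]
    a <- a[!is.na(a)]
    if (length(a) < 2L) {
      skipped <- c(skipped, rownames(angles)[ci])
      next
    }
    pr <- utils::combn(length(a), 2L)
    per[[rownames(angles)[ci]]] <- (a[pr[2, ]] - a[pr[1, ]]) %% 360
  }
  pooled <- unlist(per, use.names = FALSE) %||% numeric()
  breaks <- seq(0, 360, by = bin_deg)
  counts <- if (length(pooled)) {
    as.integer(table(cut(pooled, breaks, right = FALSE,
                         include.lowest = TRUE)))
  } else integer(length(breaks) - 1L)
  list(per_cell = per, pooled = pooled,
       histogram = data.frame(bin_start = breaks[-length(breaks)],
                              count = counts),
       skipped_cells = skipped)
}

#' Angle doubling and mean resultant length
#'
#' Doubles each angle modulo 360 (turning axially bimodal distributions
#' unimodal) and computes the mean resultant length of the doubled angles.
#'
#' @param angles Degrees (nonempty, finite).
#' @return List with `doubled` (degrees in \[0, 360)) and `r_bar` in
#'   \[0, 1\].
#' @export
double_angles <- function(angles) {
  stopifnot(length(angles) > 0L, all(is.finite(angles)))
  doubled <- (2 * angles) %% 360
  th <- doubled * pi / 180
  r_bar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  list(doubled = doubled, r_bar = r_bar)
}

#' Ensemble coherency per trial pair
#'
#' For every trial pair, the share of simultaneously recorded cells whose
#' best-match rotation equals each angle, over cells active in both trials
#' with a defined BMR. Shares are ranked 1st (highest) to 4th; rank ties
#' are broken by the smaller angle. Chance share is 0.25. Each pair is
#' labelled within- or across-context.
#'
#' @param records Data frame from [session_bmr()].
#' @param trials Trial metadata with `trial_id` and `context`.
#' @return A `coherency_table` data frame: one row per pair with shares
#'   `s0`...`s270`, ranked shares `rank1`...`rank4`, ranked angles
#'   `angle1`...`angle4`, `n_cells_included` and `comparison`
#'   ("within"/"across"). Pairs with no included cell are dropped (listed
#'   in attribute `"dropped_pairs"`).
#' @export
session_coherency <- function(records, trials) {
  angles <- c(0, 90, 180, 270)
  ctx <- stats::setNames(trials$context, trials$trial_id)
  key <- paste(records$trial_i, records$trial_j)
  rows <- list()
  dropped <- character()
  for (k in unique(key)) {
    d <- records[key == k & records$defined & records$active_both, ,
                 drop = FALSE]
    if (nrow(d) == 0L) {
      dropped <- c(dropped, k)
      next
    }
    shares <- as.numeric(table(factor(d$best_angle, levels = angles))) /
      nrow(d)
    ord <- order(-shares, angles)
    rows[[k]] <- data.frame(
      trial_i = d$trial_i[1], trial_j = d$trial_j[1],
      s0 = shares[1], s90 = shares[2], s180 = shares[3], s270 = shares[4],
      rank1 = shares[ord[1]], rank2 = shares[ord[2]],
      rank3 = shares[ord[3]], rank4 = shares[ord[4]],
      angle1 = angles[ord[1]], angle2 = angles[ord[2]],
      angle3 = angles[ord[3]], angle4 = angles[ord[4]],
      n_cells_included = nrow(d),
      comparison = if (ctx[[d$trial_i[1]]] == ctx[[d$trial_j[1]]])
        "within" else "across",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(trial_i = character(), trial_j = character(),
                      s0 = numeric(), s90 = numeric(), s180 = numeric(),
                      s270 = numeric(), rank1 = numeric(),
                      rank2 = numeric(), rank3 = numeric(),
                      rank4 = numeric(), angle1 = numeric(),
                      angle2 = numeric(), angle3 = numeric(),
                      angle4 = numeric(), n_cells_included = integer(),
                      comparison = character())
  }
  rownames(out) <- NULL
  attr(out, "dropped_pairs") <- dropped
  class(out) <- c("coherency_table", "data.frame")
  out
}

#' Joint distribution of 1st and 2nd best-match rotations
#'
#' Accumulates, over trial pairs, a unit of probability mass at the
#' (1st BMR angle, 2nd BMR angle) cell of a 4 x 4 matrix and averages
#' (per animal first when an `animal` column is present, then across
#' animals). Rows index the 1st BMR, columns the 2nd.
#'
#' @param tables A `coherency_table` (optionally filtered to one cell
#'   class and comparison type, optionally carrying an `animal` column).
#' @return List with `joint` (4 x 4 matrix, entries >= 0 summing to 1) and
#'   `marginal_first` (named length-4 vector).
#' @export
joint_bmr_distribution <- function(tables) {
  angles <- c(0, 90, 180, 270)
  one <- function(d) {
    m <- matrix(0, 4, 4, dimnames = list(angles, angles))
    for (i in seq_len(nrow(d))) {
      m[match(d$angle1[i], angles), match(d$angle2[i], angles)] <-
        m[match(d$angle1[i], angles), match(d$angle2[i], angles)] +
        1 / nrow(d)
    }
    m
  }
  joint <- if (!is.null(tables$animal)) {
    mats <- lapply(split(tables, tables$animal), one)
    Reduce(`+`, mats) / length(mats)
  } else one(tables)
  list(joint = joint, marginal_first = rowSums(joint))
}
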