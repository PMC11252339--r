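#' Stack per-cell average aligned maps into a population matrix
#'
#' @param avg_maps Named list (one per cell) of average aligned maps (as
#'   from [align_within_context()]`$average`), all on the same grid.
#' @return A `population_stack`: list with `values` (cells x pixels,
#'   undefined pixels as 0), `defined` (logical, same shape) and
#'   `cell_ids`.
#' @export
population_stack <- function(avg_maps) {
  stopifnot(length(avg_maps) >= 1L)
  vals <- do.call(rbind, lapply(avg_maps, function(m) {
    v <- as.numeric(m$rate)
    v[!as.logical(m$mask)] <- 0
    v
  }))
  def <- do.call(rbind, lapply(avg_maps, function(m) {
    as.logical(m$mask)
  }))
  structure(list(values = vals, defined = def,
                 cell_ids = names(avg_maps)),
            class = "population_stack")
}

#' Per-pixel normalized dot product between two population stacks
#'
#' At each pixel, the across-cell activity vectors from context A and B
#' give cosine similarity dot/(||a|| ||b||), in \[0, 1\] for nonnegative
#' activity. Pixels are valid only where at least one cell's average map is
#' defined in both contexts; pixels with a zero vector in either context
#' are flagged undefined (`NA`).
#'
#' @param stack_A,stack_B `population_stack` objects with identical cell
#'   order and grid.
#' @return Numeric vector over pixels (`NA` = invalid/undefined), with
#'   attribute `n_valid`.
#' @export
normalized_dot_product <- function(stack_A, stack_B) {
  stopifnot(inherits(stack_A, "population_stack"),
            inherits(stack_B, "population_stack"))
  if (!identical(stack_A$cell_ids, stack_B$cell_ids) ||
      !all(dim(stack_A$values) == dim(stack_B$values))) {
    stop("population stacks must share cell order and grid",
         call. = FALSE)
  }
  valid <- colSums(stack_A$defined) > 0 & colSums(stack_B$defined) > 0
  na2 <- colSums(stack_A$values^2)
  nb2 <- colSums(stack_B$values^2)
  num <- colSums(stack_A$values * stack_B$values)
  out <- rep(NA_real_, length(valid))
  ok <- valid & na2 > 0 & nb2 > 0
  out[ok] <- num[ok] / sqrt(na2[ok] * nb2[ok])
  attr(out, "n_valid") <- sum(ok)
  out
}

# Cosine between two maps over jointly defined pixels; NA when either
# restriction is a zero vector.
map_cosine <- function(map_w, avg, rotate = 0) {
  r <- map_w$rate; m <- map_w$mask
  if (rotate == 180) {
    r <- rot_half(r); m <- rot_half(m)
  }
  joint <- m & avg$mask
  if (!any(joint)) return(NA_real_)
  a <- r[joint]; b <- avg$rate[joint]
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 == 0 || nb2 == 0) return(NA_real_)
  sum(a * b) / sqrt(na2 * nb2)
}

#' Leave-one-out context prediction from firing location
#'
#' For each withheld trial, every eligible cell's average aligned map per
#' context is recomputed excluding that trial; the withheld trial's map is
#' compared to each context average by normalized dot product (allowing a
#' 0/180 geometric alignment of the withheld map, the better of the two),
#' cell scores are averaged, and the context with the higher average dot
#' product wins. Eligible cells have a detected field on the withheld trial
#' and at least one field-bearing trial per context among the remaining
#' trials. Ties are broken by a seeded uniform draw, recorded per trial.
#'
#' @param maps Output of [session_rate_maps()].
#' @param trials Trial metadata (`trial_id`, `context`).
#' @param cell_ids Cells to use (e.g. the FI or FS subset).
#' @param min_overlap Minimum joint pixels for within-context alignment.
#' @param tie_seed Integer seed for tie resolution.
#' @return List with `accuracy` (correct / predicted), `n_predicted`,
#'   `log` (data frame per trial: true, predicted, score_A, score_B,
#'   n_cells, tie) — unpredicted trials carry `NA` prediction and are
#'   excluded from the accuracy denominator.
#' @export
predict_context_by_location <- function(maps, trials, cell_ids,
                                        min_overlap = 20, tie_seed = 1L) {
  trial_ids <- names(maps)
  ctx <- stats::setNames(trials$context, trials$trial_id)
  has_field <- vapply(trial_ids, function(tid) {
    vapply(cell_ids, function(cid) {
      length(detect_place_fields(maps[[tid]][[cid]])) > 0L
    }, logical(1))
  }, logical(length(cell_ids)))
  if (is.null(dim(has_field))) {
    has_field <- matrix(has_field, nrow = length(cell_ids),
                        dimnames = list(cell_ids, trial_ids))
  }

  # partner trial in the other context (same within-context ordinal),
  # held out alongside the withheld trial so both context averages pool
  # the same number of trials (an unbalanced average is noisier and
  # biases the cosine comparison toward the larger context)
  ord <- stats::ave(seq_along(trial_ids), ctx[trial_ids],
                    FUN = seq_along)
  partner <- vapply(seq_along(trial_ids), function(i) {
    other <- which(ctx[trial_ids] != ctx[trial_ids[i]] & ord == ord[i])
    if (length(other)) trial_ids[other[1]] else NA_character_
  }, character(1))
  names(partner) <- trial_ids

  log_rows <- list()
  withr_seed(tie_seed, {
    for (t in trial_ids) {
      others <- setdiff(trial_ids, c(t, partner[[t]]))
      score_A <- score_B <- c()
      for (cid in cell_ids) {
        if (!has_field[cid, t]) next
        ids_A <- others[ctx[others] == "A" & has_field[cid, others]]
        ids_B <- others[ctx[others] == "B" & has_field[cid, others]]
        if (length(ids_A) == 0L || length(ids_B) == 0L) next
        avg_A <- align_within_context(
          lapply(ids_A, function(x) maps[[x]][[cid]]), min_overlap)$average
        avg_B <- align_within_context(
          lapply(ids_B, function(x) maps[[x]][[cid]]), min_overlap)$average
        w <- maps[[t]][[cid]]
        cA <- max(map_cosine(w, avg_A, 0), map_cosine(w, avg_A, 180),
                  na.rm = TRUE)
        cB <- max(map_cosine(w, avg_B, 0), map_cosine(w, avg_B, 180),
                  na.rm = TRUE)
        if (is.finite(cA) && is.finite(cB)) {
          score_A <- c(score_A, cA)
          score_B <- c(score_B, cB)
        }
      }
      if (length(score_A) == 0L) {
        log_rows[[t]] <- data.frame(trial_id = t, true = ctx[[t]],
                                    predicted = NA_character_,
                                    score_A = NA_real_, score_B = NA_real_,
                                    n_cells = 0L, tie = FALSE)
        next
      }
      sA <- mean(score_A); sB <- mean(score_B)
      tie <- abs(sA - sB) < 1e-12
      pred <- if (tie) sample(c("A", "B"), 1L)
              else if (sA > sB) "A" else "B"
      log_rows[[t]] <- data.frame(trial_id = t, true = ctx[[t]],
                                  predicted = pred, score_A = sA,
                                  score_B = sB,
                                  n_cells = length(score_A), tie = tie)
    }
  })
  log_df <- do.call(rbind, log_rows)
  rownames(log_df) <- NULL
  done <- !is.na(log_df$predicted)
  list(accuracy = if (any(done))
         mean(log_df$predicted[done] == log_df$true[done]) else NA_real_,
       n_predicted = sum(done), log = log_df)
}

#' Population context-similarity distributions for FI and FS subsets
#'
#' Builds per-context population stacks from each subset's average aligned
#' maps (cells with at least one field-bearing trial per context) and
#' returns the per-pixel normalized dot-product distributions.
#'
#' @param maps Output of [session_rate_maps()].
#' @param trials Trial metadata.
#' @param scores Data frame from [session_context_similarity()].
#' @param min_overlap Alignment overlap threshold.
#' @return Named list (`FI`, `FS`) of numeric dot-product vectors (valid
#'   pixels only).
#' @export
population_context_similarity <- function(maps, trials, scores,
                                          min_overlap = 20) {
  ctx <- stats::setNames(trials$context, trials$trial_id)
  out <- list()
  for (cls in c("FI", "FS")) {
    cells <- scores$cell_id[scores$class == cls]
    if (length(cells) == 0L) {
      out[[cls]] <- numeric()
      next
    }
    avg_A <- list(); avg_B <- list()
    for (cid in cells) {
      has_field <- vapply(names(maps), function(tid) {
        length(detect_place_fields(maps[[tid]][[cid]])) > 0L
      }, logical(1))
      ids_A <- names(maps)[has_field & ctx[names(maps)] == "A"]
      ids_B <- names(maps)[has_field & ctx[names(maps)] == "B"]
      if (length(ids_A) == 0L || length(ids_B) == 0L) next
      a_avg <- align_within_context(
        lapply(ids_A, function(x) maps[[x]][[cid]]), min_overlap)$average
      b_avg <- align_within_context(
        lapply(ids_B, function(x) maps[[x]][[cid]]), min_overlap)$average
      # each cell's within-context alignment fixes orientation only up to
      # a global flip; align the B average to the A average (best of
      # 0/180) before stacking, as for the single-cell similarity score
      cs <- context_similarity(a_avg, b_avg, min_overlap = min_overlap)
      if (identical(cs$alignment, 180)) {
        b_avg$rate <- rot_half(b_avg$rate)
        b_avg$mask <- rot_half(b_avg$mask)
        b_avg$count <- rot_half(b_avg$count)
      }
      avg_A[[cid]] <- a_avg
      avg_B[[cid]] <- b_avg
    }
    if (length(avg_A) == 0L) {
      out[[cls]] <- numeric()
      next
    }
    dp <- normalized_dot_product(population_stack(avg_A),
                                 population_stack(avg_B))
    out[[cls]] <- dp[!is.na(dp)]
  }
  out
}
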