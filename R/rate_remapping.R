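#' Absolute rate-difference matrix for one cell
#'
#' Symmetric trials x trials matrix of |mean rate(i) - mean rate(j)|.
#' Trials with undefined rates are masked out (rows and columns `NA`).
#'
#' @param cell_rates Named numeric vector of per-trial mean rates.
#' @return A `rate_difference_matrix`: the matrix, with attribute
#'   `defined` (logical per trial). Fewer than 2 defined trials is an
#'   error.
#' @export
rate_difference_matrix <- function(cell_rates) {
  ok <- is.finite(cell_rates)
  if (sum(ok) < 2L) {
    stop("need at least 2 trials with defined rates", call. = FALSE)
  }
  m <- abs(outer(cell_rates, cell_rates, "-"))
  m[!ok, ] <- NA_real_
  m[, !ok] <- NA_real_
  diag(m)[ok] <- 0
  structure(m, defined = ok, class = c("rate_difference_matrix", "matrix"))
}

#' Within- vs across-context mean rate difference
#'
#' Averages the off-diagonal entries of a rate-difference matrix over
#' same-context pairs (both A-A and B-B quadrants pooled) and over
#' mixed-context pairs.
#'
#' @param mat A `rate_difference_matrix` (trial ids in dimnames).
#' @param trials Trial metadata with `trial_id` and `context`.
#' @return List with `within`, `across` (`NA` with flag when a mask is
#'   empty) and the pair counts.
#' @export
within_across_summary <- function(mat, trials) {
  ids <- rownames(mat)
  ctx <- trials$context[match(ids, trials$trial_id)]
  n <- length(ids)
  pair <- upper.tri(matrix(0, n, n))
  same <- outer(ctx, ctx, "==") & pair
  mixed <- outer(ctx, ctx, "!=") & pair
  w_vals <- mat[same]
  a_vals <- mat[mixed]
  w_vals <- w_vals[!is.na(w_vals)]
  a_vals <- a_vals[!is.na(a_vals)]
  list(within = if (length(w_vals)) mean(w_vals)
                else structure(NA_real_, undefined = TRUE),
       across = if (length(a_vals)) mean(a_vals)
                else structure(NA_real_, undefined = TRUE),
       n_within = length(w_vals), n_across = length(a_vals))
}

#' Session-level rate remapping summary
#'
#' Builds each eligible cell's rate-difference matrix from per-trial mean
#' rates, summarises within- vs across-context differences per cell, and
#' returns the cellwise-mean animal matrix.
#'
#' @param rates Cells x trials mean-rate matrix.
#' @param trials Trial metadata.
#' @param cells Optional subset of cell ids (defaults to all with >= 2
#'   defined rates; cells failing that are excluded and listed).
#' @return List with `per_cell` (data frame: cell_id, within, across),
#'   `animal_matrix` (cellwise mean of the difference matrices) and
#'   `excluded_cells`.
#' @export
session_rate_remapping <- function(rates, trials, cells = NULL) {
  if (is.null(cells)) cells <- rownames(rates)
  ok <- cells[rowSums(is.finite(rates[cells, , drop = FALSE])) >= 2]
  excluded <- setdiff(cells, ok)
  mats <- lapply(ok, function(cid) rate_difference_matrix(rates[cid, ]))
  per <- do.call(rbind, lapply(seq_along(ok), function(i) {
    s <- within_across_summary(mats[[i]], trials)
    data.frame(cell_id = ok[i], within = as.numeric(s$within),
               across = as.numeric(s$across), stringsAsFactors = FALSE)
  }))
  animal <- if (length(mats)) {
    arr <- simplify2array(lapply(mats, unclass))
    apply(arr, c(1, 2), mean, na.rm = TRUE)
  } else NULL
  list(per_cell = per, animal_matrix = animal, excluded_cells = excluded)
}
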