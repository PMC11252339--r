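#' Detect place fields in a rate map
#'
#' A place field is a 4-connected set of sampled pixels whose rates exceed
#' the 95th percentile of the sampled-pixel rate distribution (percentile by
#' linear interpolation). Fields are returned sorted by area (pixel count)
#' descending, so callers honouring the largest-field rule use
#' `fields[[1]]`.
#'
#' @param map A `rate_map` or `square_map`.
#' @param percentile Threshold percentile (default 95).
#' @return List of `place_field` objects: `pixels` (2-column matrix of
#'   x/y bin indices), `area`, `weighted_centroid` (cm), `peak_rate`, and
#'   `center_out_angle` (degrees in \[0, 360), `NA` when the centroid
#'   coincides with the map center). Empty list for an all-zero or empty
#'   map.
#' @export
detect_place_fields <- function(map, percentile = 95) {
  stopifnot(inherits(map, "rate_map"))
  if (map$empty || !any(map$mask)) return(list())
  vals <- map$rate[map$mask]
  if (all(vals == 0)) return(list())
  thr <- stats::quantile(vals, percentile / 100, names = FALSE, type = 7)
  supra <- map$mask & !is.na(map$rate) & map$rate > thr
  if (!any(supra)) return(list())

  labels <- label_components_4(supra)
  center <- c(nrow(map$rate) * map$bin_x / 2,
              ncol(map$rate) * map$bin_y / 2)
  fields <- lapply(seq_len(max(labels)), function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    w <- map$rate[labels == k]
    cx <- sum((idx[, 1] - 0.5) * map$bin_x * w) / sum(w)
    cy <- sum((idx[, 2] - 0.5) * map$bin_y * w) / sum(w)
    structure(list(pixels = unname(idx), area = nrow(idx),
                   weighted_centroid = c(cx, cy),
                   peak_rate = max(w),
                   center_out_angle = center_out_angle_xy(cx, cy, center)),
              class = "place_field")
  })
  fields[order(vapply(fields, `[[`, 0L, "area"), decreasing = TRUE)]
}

# 4-connected component labelling on a logical matrix (tiny grids; plain
# iterative flood fill).
label_components_4 <- function(m) {
  labels <- matrix(0L, nrow(m), ncol(m))
  nx <- nrow(m); ny <- ncol(m)
  todo <- which(m)
  lab <- 0L
  for (start in todo) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    stack <- start
    labels[start] <- lab
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- ((p - 1L) %% nx) + 1L
      j <- ((p - 1L) %/% nx) + 1L
      nb <- c(if (i > 1L) p - 1L, if (i < nx) p + 1L,
              if (j > 1L) p - nx, if (j < ny) p + nx)
      nb <- nb[m[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      stack <- c(stack, nb)
    }
  }
  labels
}

#' Center-out angle of a place field
#'
#' Angle from the map center to the field's rate-weighted centroid;
#' `atan2` convention, 0 degrees toward +x, counter-clockwise, wrapped to
#' \[0, 360).
#'
#' @param field A `place_field`.
#' @param map_center Numeric `c(x, y)` in cm.
#' @return Degrees in \[0, 360), or `NA` (attribute `undefined = TRUE`)
#'   when the centroid coincides with the center.
#' @export
center_out_angle <- function(field, map_center) {
  stopifnot(inherits(field, "place_field"))
  center_out_angle_xy(field$weighted_centroid[1],
                      field$weighted_centroid[2], map_center)
}

center_out_angle_xy <- function(cx, cy, center) {
  dx <- cx - center[1]
  dy <- cy - center[2]
  if (abs(dx) < 1e-12 && abs(dy) < 1e-12) {
    return(structure(NA_real_, undefined = TRUE))
  }
  (atan2(dy, dx) * 180 / pi) %% 360
}

#' Center-out angles for every cell and trial of a session
#'
#' Uses each cell's largest field per trial; `NA` where a cell has no field
#' on a trial.
#'
#' @param maps Output of [session_rate_maps()] (native rectangular maps).
#' @return Matrix cells x trials of angles in degrees.
#' @export
session_center_out_angles <- function(maps) {
  trial_ids <- names(maps)
  cell_ids <- names(maps[[1]])
  ang <- matrix(NA_real_, length(cell_ids), length(trial_ids),
                dimnames = list(cell_ids, trial_ids))
  for (ti in seq_along(maps)) {
    for (ci in seq_along(cell_ids)) {
      f <- detect_place_fields(maps[[ti]][[ci]])
      if (length(f)) ang[ci, ti] <- f[[1]]$center_out_angle
    }
  }
  ang
}
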