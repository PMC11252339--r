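#' Occupancy-normalised place map for one cell and trial
#'
#' Bins speed-filtered position samples and activity-train event weights
#' onto a pixel grid, smooths the activity and time maps with the same
#' truncated Gaussian kernel, and divides. Only samples moving faster than
#' `speed_cutoff` contribute to either map. Pixels whose smoothed occupancy
#' falls below `occupancy_min` are masked out and carry no rate value.
#'
#' The native grid is 1 cm x 1 cm; passing `bin_y = 1.5` performs the
#' anisotropic compression of the 20 x 30 cm chamber to a 20 x 20 square
#' by re-binning the raw data (see [compress_to_square()]).
#'
#' @param traj A `trajectory` (columns `t`, `x`, `y`, `speed`).
#' @param act An `activity_train` (columns `t`, `w`), or `NULL` for an
#'   occupancy-only map.
#' @param bin_x,bin_y Bin sizes in cm.
#' @param sigma_cm Gaussian smoothing width (cm); `0` disables smoothing.
#' @param speed_cutoff Minimum speed (cm/s) for a sample to count.
#' @param occupancy_min Smoothed-occupancy threshold (s) defining sampled
#'   pixels.
#' @param chamber Chamber extent `c(x, y)` in cm.
#' @param smooth_mode `"separate"` smooths the activity and time maps
#'   independently and then divides (default); `"ratio"` divides the raw
#'   maps and smooths the quotient.
#' @return A `rate_map`: list with `rate` (matrix, x bins in rows, `NA`
#'   off-mask), `occupancy` (smoothed seconds), `mask` (logical),
#'   `bin_x`, `bin_y`, `sigma_cm`, and `empty` flag (`TRUE` when no sample
#'   survived the speed filter).
#' @export
compute_rate_map <- function(traj, act, bin_x = 1, bin_y = 1,
                             sigma_cm = 3, speed_cutoff = 2,
                             occupancy_min = 0.05, chamber = c(20, 30),
                             smooth_mode = c("separate", "ratio")) {
  smooth_mode <- match.arg(smooth_mode)
  occ <- trial_occupancy(traj, bin_x, bin_y, sigma_cm, speed_cutoff,
                         occupancy_min, chamber)
  cell_rate_map(occ, act, smooth_mode)
}

# Trial-level occupancy geometry, reusable across simultaneously recorded
# cells (the expensive shared part of compute_rate_map).
trial_occupancy <- function(traj, bin_x = 1, bin_y = 1, sigma_cm = 3,
                            speed_cutoff = 2, occupancy_min = 0.05,
                            chamber = c(20, 30)) {
  nx <- as.integer(round(chamber[1] / bin_x))
  ny <- as.integer(round(chamber[2] / bin_y))
  n <- nrow(traj)
  dt <- if (n > 1L) stats::median(diff(traj$t)) else 1
  keep <- traj$speed > speed_cutoff
  ix <- pmin.int(pmax.int(floor(traj$x / bin_x) + 1L, 1L), nx)
  iy <- pmin.int(pmax.int(floor(traj$y / bin_y) + 1L, 1L), ny)
  pix <- (iy - 1L) * nx + ix

  occ_raw <- matrix(0, nx, ny)
  if (any(keep)) {
    tb <- tabulate(pix[keep], nbins = nx * ny)
    occ_raw[] <- tb * dt
  }
  sx <- smoothing_matrix(nx, bin_x, sigma_cm)
  sy <- smoothing_matrix(ny, bin_y, sigma_cm)
  occ_smooth <- sx %*% occ_raw %*% t(sy)
  list(nx = nx, ny = ny, dt = dt, bin_x = bin_x, bin_y = bin_y,
       sigma_cm = sigma_cm, chamber = chamber,
       frame_keep = keep, frame_pix = pix, t0 = traj$t[1],
       frame_times = traj$t,
       occ_raw = occ_raw, occ_smooth = occ_smooth,
       sx = sx, sy = sy,
       mask = occ_smooth >= occupancy_min,
       empty = !any(keep))
}

# Rate map for one cell given precomputed trial occupancy.
cell_rate_map <- function(occ, act, smooth_mode = "separate") {
  amap <- matrix(0, occ$nx, occ$ny)
  if (!is.null(act) && nrow(act) > 0L) {
    fi <- event_frames(act$t, occ$frame_times)
    ok <- occ$frame_keep[fi]
    if (any(ok)) {
      px <- occ$frame_pix[fi[ok]]
      w <- act$w[ok]
      sums <- rowsum(w, px)
      amap[as.integer(rownames(sums))] <- sums
    }
  }
  if (occ$empty) {
    rate <- matrix(NA_real_, occ$nx, occ$ny)
    mask <- matrix(FALSE, occ$nx, occ$ny)
  } else if (smooth_mode == "separate") {
    asm <- occ$sx %*% amap %*% t(occ$sy)
    rate <- asm / occ$occ_smooth
    mask <- occ$mask
    rate[!mask] <- NA_real_
  } else {
    q <- amap / occ$occ_raw
    q[occ$occ_raw == 0] <- 0
    rate <- occ$sx %*% q %*% t(occ$sy)
    mask <- occ$mask
    rate[!mask] <- NA_real_
  }
  structure(list(rate = rate, occupancy = occ$occ_smooth,
                 activity_raw = amap, mask = mask,
                 bin_x = occ$bin_x, bin_y = occ$bin_y,
                 sigma_cm = occ$sigma_cm, chamber = occ$chamber,
                 empty = occ$empty),
            class = if (occ$nx == occ$ny) c("square_map", "rate_map")
                    else "rate_map")
}

# Nearest-frame index for each event time.
event_frames <- function(times, frame_times) {
  n <- length(frame_times)
  if (n == 1L) return(rep(1L, length(times)))
  dt <- frame_times[2] - frame_times[1]
  pmin.int(pmax.int(as.integer(round((times - frame_times[1]) / dt)) + 1L,
                    1L), n)
}

# 1-D Gaussian smoothing matrix, truncated at 4 sigma and row-renormalised
# inside the chamber (no bleed across walls). sigma_cm = 0 -> identity.
smoothing_matrix <- function(nbins, bin_cm, sigma_cm) {
  if (sigma_cm <= 0) return(diag(nbins))
  centers <- (seq_len(nbins) - 0.5) * bin_cm
  d <- outer(centers, centers, "-")
  w <- exp(-d^2 / (2 * sigma_cm^2))
  w[abs(d) > 4 * sigma_cm] <- 0
  w / rowSums(w)
}

#' Compress a rectangular trial to a 20 x 20 square map
#'
#' Anisotropic re-binning of the raw data (x into 1 cm bins, y into 1.5 cm
#' bins), not a resampling of the smoothed rectangular map.
#'
#' @inheritParams compute_rate_map
#' @return A `square_map` (a `rate_map` with equal bin counts per axis).
#' @export
compress_to_square <- function(traj, act, sigma_cm = 3, speed_cutoff = 2,
                               occupancy_min = 0.05, chamber = c(20, 30),
                               smooth_mode = "separate") {
  if (abs(chamber[2] / chamber[1] - 1.5) > 1e-9) {
    stop("square compression expects a 2:3 chamber", call. = FALSE)
  }
  compute_rate_map(traj, act, bin_x = chamber[1] / 20,
                   bin_y = chamber[2] / 20, sigma_cm = sigma_cm,
                   speed_cutoff = speed_cutoff,
                   occupancy_min = occupancy_min, chamber = chamber,
                   smooth_mode = smooth_mode)
}

#' Rate maps for every cell and trial of a session
#'
#' Computes per-trial occupancy once and reuses it for all simultaneously
#' recorded cells.
#'
#' @param bundle A `session_bundle`.
#' @param square If `TRUE`, build 20 x 20 anisotropically binned maps;
#'   otherwise native 1 cm maps.
#' @param ... Passed to [trial_occupancy()] (smoothing, thresholds).
#' @return List over trials, each a list over cells of `rate_map` objects.
#' @export
session_rate_maps <- function(bundle, square = FALSE, ...) {
  cfg <- list(...)
  bins <- if (square) {
    ch <- attr(bundle$trajectories[[1]], "chamber") %||% c(20, 30)
    list(bin_x = ch[1] / 20, bin_y = ch[2] / 20)
  } else list(bin_x = 1, bin_y = 1)
  out <- lapply(names(bundle$trajectories), function(id) {
    occ <- do.call(trial_occupancy,
                   c(list(traj = bundle$trajectories[[id]]), bins, cfg))
    maps <- lapply(bundle$activity[[id]], function(a) cell_rate_map(occ, a))
    maps
  })
  names(out) <- names(bundle$trajectories)
  out
}

#' Trial-level firing-rate statistic
#'
#' Mean rate = total speed-filtered event weight divided by total filtered
#' time; peak rate = maximum sampled-pixel value of the trial's (smoothed)
#' rate map.
#'
#' @param act An `activity_train`.
#' @param traj A `trajectory`.
#' @param mode "mean" or "peak".
#' @param map Optional precomputed `rate_map` (required for "peak" to be
#'   cheap; computed on the fly otherwise).
#' @param speed_cutoff Movement threshold (cm/s).
#' @return Rate in events/s, or `NA` with attribute `undefined = TRUE` when
#'   no time survives the filter.
#' @export
trial_rate_stats <- function(act, traj, mode = c("mean", "peak"),
                             map = NULL, speed_cutoff = 2) {
  mode <- match.arg(mode)
  if (mode == "mean") {
    keep <- traj$speed > speed_cutoff
    total_t <- sum(keep) * (if (nrow(traj) > 1L)
      stats::median(diff(traj$t)) else 1)
    if (total_t <= 0) {
      return(structure(NA_real_, undefined = TRUE))
    }
    if (is.null(act) || nrow(act) == 0L) return(0)
    fi <- event_frames(act$t, traj$t)
    sum(act$w[keep[fi]]) / total_t
  } else {
    if (is.null(map)) map <- compute_rate_map(traj, act,
                                              speed_cutoff = speed_cutoff)
    if (map$empty || !any(map$mask)) {
      return(structure(NA_real_, undefined = TRUE))
    }
    max(map$rate[map$mask])
  }
}

#' Spatial information content of a rate map
#'
#' Skaggs information in bits per event:
#' \deqn{\sum_i p_i \frac{\lambda_i}{\lambda}
#'       \log_2 \frac{\lambda_i}{\lambda}}
#' over sampled pixels, with occupancy probabilities \eqn{p_i} and overall
#' mean rate \eqn{\lambda = \sum_i p_i \lambda_i}. Zero-rate pixels
#' contribute nothing.
#'
#' @param map A `rate_map`.
#' @return Bits per event, or `NA` with attribute `undefined = TRUE` when
#'   the mean rate is zero.
#' @export
spatial_information <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  if (map$empty || !any(map$mask)) {
    return(structure(NA_real_, undefined = TRUE))
  }
  p <- map$occupancy[map$mask]
  p <- p / sum(p)
  lam_i <- map$rate[map$mask]
  lam <- sum(p * lam_i)
  if (lam <= 0) return(structure(NA_real_, undefined = TRUE))
  pos <- lam_i > 0
  sum(p[pos] * (lam_i[pos] / lam) * log2(lam_i[pos] / lam))
}
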