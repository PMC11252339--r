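#' Map video-frame positions into the canonical chamber frame
#'
#' Estimates the planar projective transform (homography) that carries the
#' four marked chamber corners onto the canonical rectangle, so that the
#' short wall adjacent to the rewarded corner lands on the same canonical
#' side in every trial and both contexts, and applies it to the position
#' samples.
#'
#' @param raw_xy Two-column matrix/data.frame of positions in video
#'   coordinates.
#' @param chamber_corners 4 x 2 matrix of the chamber corners in video
#'   coordinates, in counter-clockwise winding starting from the corner
#'   that maps to the canonical origin when `trial_orientation = 0`.
#' @param trial_orientation Physical chamber orientation in degrees
#'   (multiple of 90); the corner correspondence is advanced accordingly.
#' @param chamber Canonical chamber extent `c(x, y)` in cm.
#' @return Matrix of positions in cm in the canonical frame, with the
#'   estimated 3 x 3 homography in attribute `"homography"`.
#' @export
align_positions <- function(raw_xy, chamber_corners, trial_orientation = 0,
                            chamber = c(20, 30)) {
  raw_xy <- as.matrix(raw_xy)
  chamber_corners <- as.matrix(chamber_corners)
  stopifnot(ncol(raw_xy) == 2L, nrow(chamber_corners) == 4L,
            trial_orientation %% 90 == 0)
  canon <- rbind(c(0, 0), c(chamber[1], 0), chamber, c(0, chamber[2]))
  shift <- (as.integer(trial_orientation) %/% 90L) %% 4L
  src <- chamber_corners[((seq_len(4L) - 1L - shift) %% 4L) + 1L, ,
                         drop = FALSE]
  H <- fit_homography(src, canon)
  out <- apply_homography(H, raw_xy)
  attr(out, "homography") <- H
  out
}

# Direct linear transform for 4 point correspondences (h33 fixed at 1).
fit_homography <- function(src, dst) {
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]
    u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b), error = function(e) {
    stop("degenerate chamber corners (collinear or repeated)",
         call. = FALSE)
  })
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

apply_homography <- function(H, xy) {
  p <- cbind(xy, 1) %*% t(H)
  cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
}
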