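# Shared fixtures, built in code.

# A rate_map object from a plain matrix (bin size 1 cm unless stated).
toy_map <- function(rate, bin_x = 1, bin_y = 1, mask = NULL,
                    occupancy = NULL) {
  rate <- as.matrix(rate)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(rate), ncol(rate))
  if (is.null(occupancy)) occupancy <- matrix(1, nrow(rate), ncol(rate))
  r <- rate
  r[!mask] <- NA_real_
  structure(list(rate = r, occupancy = occupancy,
                 activity_raw = rate, mask = mask,
                 bin_x = bin_x, bin_y = bin_y, sigma_cm = 0,
                 chamber = c(nrow(rate) * bin_x, ncol(rate) * bin_y),
                 empty = FALSE),
            class = if (nrow(rate) == ncol(rate))
              c("square_map", "rate_map") else "rate_map")
}

# Hand-built trajectory: constant dt, speeds from positions.
toy_trajectory <- function(x, y, dt = 0.1) {
  tr <- data.frame(t = (seq_along(x) - 1) * dt, x = x, y = y)
  tr$speed <- reorientr:::frame_speed(tr)
  class(tr) <- c("trajectory", "data.frame")
  tr
}

toy_train <- function(t, w = rep(1, length(t))) {
  tr <- data.frame(t = t, w = w)
  class(tr) <- c("activity_train", "data.frame")
  tr
}

# Small fast study config used across tests.
quick_config <- function(...) {
  args <- list(n_animals = 1, n_days = 1, trial_duration_s = 60,
               frame_rate_hz = 20, n_fi_cells = 12, n_fs_cells = 3)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# One cached default-ish session bundle shared by read-only tests.
shared_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_study(quick_config(seed = 42))$animals[[1]][[1]]
    }
    cache
  }
})

shared_maps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- session_rate_maps(shared_session())
    cache
  }
})

shared_square_maps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- session_rate_maps(shared_session(), square = TRUE)
    }
    cache
  }
})
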