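#' Configuration for the synthetic two-context reorientation study
#'
#' Bundles every parameter of the synthetic-session generator. The defaults
#' describe a three-day study in which an animal runs 12 trials per day
#' (6 per context) in a 20 x 30 cm rectangular chamber, a majority of cells
#' align to chamber geometry in both contexts (feature-insensitive, FI) and a
#' 20% minority remaps 180 degrees across contexts (feature-sensitive, FS),
#' across-context mean-rate gain grows over days, and the first-dig choice on
#' the rewarded axis is coupled to the per-trial ensemble orientation.
#'
#' @param n_animals Number of animals to simulate.
#' @param n_days Number of study days.
#' @param trials_per_day Trials per day; must be even (equal counts per
#'   context, contexts alternate A, B, A, ...).
#' @param chamber_x_cm,chamber_y_cm Chamber extent in cm. Must be in 2:3
#'   ratio so the anisotropic square compression yields a 20 x 20 grid.
#' @param trial_duration_s Trial length in seconds (at most 180).
#' @param frame_rate_hz Position/activity sampling rate.
#' @param n_fi_cells,n_fs_cells Number of feature-insensitive and
#'   feature-sensitive cells.
#' @param field_sigma_cm Gaussian tuning width of place fields.
#' @param peak_rate_hz In-field peak event rate.
#' @param noise_rate_hz Spatially uniform baseline event rate.
#' @param coherence_by_day Per-day probability that a cell follows the
#'   trial's ensemble orientation (non-followers take the opposite
#'   geometric orientation). Length `n_days` or scalar.
#' @param fs_context_offset_deg Extra rotation of FS fields in context B
#'   relative to context A. The default 90 places FS fields on the opposite
#'   geometric axis across contexts, which survives the 0/180 geometric
#'   alignment and is what makes the cells feature-sensitive. An offset of
#'   180 is the known degenerate case — it is absorbed by across-context
#'   alignment, and such cells classify as feature-insensitive.
#' @param rate_gain_by_day Multiplicative mean-rate gain applied in context
#'   B relative to context A, per day. Length `n_days` or scalar.
#' @param dig_probs_by_day Matrix (`n_days` x 4) of categorical first-dig
#'   weights over corners C, G, N, F; rows must sum to 1.
#' @param p_dig_follows_orientation Probability that, when the first dig is
#'   on the rewarded axis, the C-vs-G choice matches the trial's ensemble
#'   orientation (0 deg -> C, 180 deg -> G).
#' @param fs_identity_retention Probability that an FS cell keeps FS
#'   behaviour on the next day; FI identities always persist.
#' @param seed Master integer seed; all per-(animal, day, trial) streams
#'   are derived from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_animals = 1, n_fi_cells = 4, n_fs_cells = 1)
#' cfg$trials_per_day
#' @export
sim_config <- function(n_animals = 4,
                       n_days = 3,
                       trials_per_day = 12,
                       chamber_x_cm = 20,
                       chamber_y_cm = 30,
                       trial_duration_s = 90,
                       frame_rate_hz = 20,
                       n_fi_cells = 16,
                       n_fs_cells = 4,
                       field_sigma_cm = 4,
                       peak_rate_hz = 8,
                       noise_rate_hz = 0.2,
                       coherence_by_day = c(0.85, 0.90, 0.95),
                       fs_context_offset_deg = 90,
                       rate_gain_by_day = c(1.0, 1.5, 2.0),
                       dig_probs_by_day = NULL,
                       p_dig_follows_orientation = 0.8,
                       fs_identity_retention = 0.3,
                       seed = 1L) {
  if (is.null(dig_probs_by_day)) {
    dig_probs_by_day <- rbind(
      c(0.375, 0.375, 0.125, 0.125),
      c(0.550, 0.200, 0.125, 0.125),
      c(0.600, 0.150, 0.125, 0.125)
    )[rep_len(seq_len(3), n_days), , drop = FALSE]
  }
  dig_probs_by_day <- matrix(as.numeric(dig_probs_by_day), ncol = 4,
                             dimnames = list(NULL, c("C", "G", "N", "F")))
  if (nrow(dig_probs_by_day) == 1L) {
    dig_probs_by_day <- dig_probs_by_day[rep(1L, n_days), , drop = FALSE]
  }

  cfg <- list(
    n_animals = as.integer(n_animals),
    n_days = as.integer(n_days),
    trials_per_day = as.integer(trials_per_day),
    chamber_x_cm = chamber_x_cm,
    chamber_y_cm = chamber_y_cm,
    trial_duration_s = trial_duration_s,
    frame_rate_hz = frame_rate_hz,
    n_fi_cells = as.integer(n_fi_cells),
    n_fs_cells = as.integer(n_fs_cells),
    field_sigma_cm = field_sigma_cm,
    peak_rate_hz = peak_rate_hz,
    noise_rate_hz = noise_rate_hz,
    coherence_by_day = rep_len(coherence_by_day, n_days),
    fs_context_offset_deg = fs_context_offset_deg,
    rate_gain_by_day = rep_len(rate_gain_by_day, n_days),
    dig_probs_by_day = dig_probs_by_day,
    p_dig_follows_orientation = p_dig_follows_orientation,
    fs_identity_retention = fs_identity_retention,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_animals < 1L || cfg$n_days < 1L) {
    stop("n_animals and n_days must be positive", call. = FALSE)
  }
  if (cfg$trials_per_day < 2L || cfg$trials_per_day %% 2L != 0L) {
    stop("trials_per_day must be even (equal counts per context)",
         call. = FALSE)
  }
  if (cfg$trial_duration_s <= 0 || cfg$trial_duration_s > 180) {
    stop("trial_duration_s must be in (0, 180]", call. = FALSE)
  }
  if (cfg$frame_rate_hz <= 0) {
    stop("frame_rate_hz must be positive", call. = FALSE)
  }
  if (abs(cfg$chamber_x_cm / cfg$chamber_y_cm - 2 / 3) > 1e-9) {
    stop("chamber_x_cm : chamber_y_cm must be 2 : 3", call. = FALSE)
  }
  probs <- c(cfg$coherence_by_day, cfg$p_dig_follows_orientation,
             cfg$fs_identity_retention, as.vector(cfg$dig_probs_by_day))
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(cfg$dig_probs_by_day) != cfg$n_days ||
      any(abs(rowSums(cfg$dig_probs_by_day) - 1) > 1e-8)) {
    stop("dig_probs_by_day must have n_days rows summing to 1",
         call. = FALSE)
  }
  if (!(cfg$fs_context_offset_deg %in% c(0, 90, 180, 270))) {
    stop("fs_context_offset_deg must be a quarter-turn multiple",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Derive a reproducible sub-seed for a named simulation stream
#'
#' One RNG stream per (animal, day, trial, stage) so any stage can be
#' regenerated independently of the others. Plain polynomial hash reduced
#' modulo 2^31 - 1; collisions across distinct index tuples are not
#' possible within the supported ranges (stage < 11, trial < 97,
#' day < 89, animal unbounded via modular wrap).
#'
#' @param master Master seed (integer).
#' @param animal,day,trial,stage Stream indices (0 allowed).
#' @return A positive integer seed below 2^31.
#' @keywords internal
sub_seed <- function(master, animal = 0L, day = 0L, trial = 0L, stage = 0L) {
  m <- 2147483647
  h <- (as.numeric(master) %% m)
  for (k in c(animal, day, trial, stage)) {
    h <- (h * 1103 + as.numeric(k) + 7) %% m
  }
  as.integer(h %% (m - 2) + 1)
}
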