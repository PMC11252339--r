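#' Dig-location proportions
#'
#' Tabulates first- (or second-) dig choices over the four corner codes
#' C (correct), G (geometric equivalent), N (near) and F (far), optionally
#' grouped by day and/or context. Groups with no scorable digs are reported
#' with `n = 0` and `NA` proportions rather than silent zeros.
#'
#' @param trials Data frame of trial records with columns `dig1`, `dig2`,
#'   `day`, `context` (as produced by [generate_study()]).
#' @param group_by Character vector of grouping columns, subset of
#'   `c("day", "context")`.
#' @param dig_rank 1 for the first dig, 2 for the second.
#' @return Data frame with grouping columns, `corner`, `n` and `prop`;
#'   proportions within each group sum to 1 (or are `NA` for empty groups).
#' @export
dig_proportions <- function(trials, group_by = character(), dig_rank = 1L) {
  stopifnot(nrow(trials) > 0L, dig_rank %in% c(1L, 2L))
  stopifnot(all(group_by %in% c("day", "context")))
  corners <- c("C", "G", "N", "F")
  dig <- trials[[paste0("dig", dig_rank)]]

  key <- if (length(group_by)) {
    interaction(trials[group_by], drop = FALSE, lex.order = TRUE)
  } else factor(rep("all", nrow(trials)))

  out <- do.call(rbind, lapply(levels(key), function(k) {
    d <- dig[key == k]
    d <- d[!is.na(d)]
    n <- table(factor(d, levels = corners))
    grp <- if (length(group_by)) {
      row <- trials[key == k, group_by, drop = FALSE]
      if (nrow(row) == 0L) {
        parts <- strsplit(k, ".", fixed = TRUE)[[1]]
        row <- as.data.frame(as.list(parts), col.names = group_by)
      } else row[1L, , drop = FALSE]
    } else data.frame(row.names = 1L)
    cbind(grp[rep(1L, 4L), , drop = FALSE],
          data.frame(corner = corners, n = as.integer(n),
                     prop = if (sum(n) == 0L) rep(NA_real_, 4L)
                            else as.numeric(n) / sum(n),
                     row.names = NULL))
  }))
  rownames(out) <- NULL
  out
}

#' Rewarded- vs unrewarded-axis dig proportions per context
#'
#' The rewarded geometric axis is the diagonal through C and G; the
#' unrewarded one runs through N and F. Distinct dominant axes per context
#' indicate that the animal discriminates the contexts.
#'
#' @inheritParams dig_proportions
#' @return Data frame with `context`, `axis` ("rewarded"/"unrewarded"),
#'   `n` and `prop`; the two proportions sum to 1 within each context.
#' @export
axis_proportions <- function(trials, dig_rank = 1L) {
  props <- dig_proportions(trials, group_by = "context",
                           dig_rank = dig_rank)
  props$axis <- ifelse(props$corner %in% c("C", "G"),
                       "rewarded", "unrewarded")
  agg <- stats::aggregate(cbind(n = props$n) ~ context + axis, data = props,
                          FUN = sum)
  agg$prop <- stats::ave(agg$n, agg$context,
                         FUN = function(v) if (sum(v) == 0) NA_real_
                                           else v / sum(v))
  agg[order(agg$context, agg$axis), ]
}

#' Bernoulli dig model
#'
#' Container for the Bayes-factor comparison of a point-null success
#' probability against a uniform alternative over an interval. The C/G
#' model tests digging on the rewarded geometric axis (null 0.5,
#' alternative uniform on (0.5, 0.9)); the C model tests digging in the
#' correct corner with contexts pooled (null 0.25, alternative uniform on
#' (0.25, 0.9)).
#'
#' @param z Number of successes.
#' @param N Number of trials.
#' @param model "cg" or "c", or supply `theta_null`/`theta_range` directly.
#' @param theta_null Point-null success probability.
#' @param theta_range Integration interval (a, b) of the alternative.
#' @return Object of class `bernoulli_dig_model`.
#' @export
bernoulli_dig_model <- function(z, N, model = c("cg", "c"),
                                theta_null = NULL, theta_range = NULL) {
  if (length(N) != 1L || N < 1L) stop("N must be >= 1", call. = FALSE)
  if (z < 0L || z > N) stop("z must satisfy 0 <= z <= N", call. = FALSE)
  if (is.null(theta_null)) {
    model <- match.arg(model)
    theta_null <- if (model == "cg") 0.5 else 0.25
    theta_range <- if (model == "cg") c(0.5, 0.9) else c(0.25, 0.9)
  }
  stopifnot(length(theta_range) == 2L, theta_range[1] < theta_range[2],
            theta_range[1] > 0, theta_range[2] < 1,
            theta_null > 0, theta_null < 1)
  structure(list(z = as.integer(z), N = as.integer(N),
                 theta_null = theta_null, theta_range = theta_range),
            class = "bernoulli_dig_model")
}

#' Log Bayes factor of a Bernoulli dig model
#'
#' Evaluates
#' \deqn{BF = \frac{\frac{1}{b-a}\int_a^b \theta^z (1-\theta)^{N-z}\,d\theta}
#'                 {\theta_0^z (1-\theta_0)^{N-z}}}
#' in closed form through regularised incomplete-beta differences
#' (`pbeta`/`lbeta` on the log scale), returning the natural logarithm.
#' Finite for all valid (z, N).
#'
#' @param model A [bernoulli_dig_model()].
#' @return Natural-log Bayes factor (positive favours the alternative).
#' @examples
#' # 10 rewarded-axis digs out of 10:
#' bayes_factor(bernoulli_dig_model(10, 10, "cg"))  # about 4.29
#' @export
bayes_factor <- function(model) {
  stopifnot(inherits(model, "bernoulli_dig_model"))
  z <- model$z; N <- model$N
  a <- model$theta_range[1]; b <- model$theta_range[2]
  t0 <- model$theta_null
  # int_a^b theta^z (1-theta)^(N-z) dtheta
  #   = B(z+1, N-z+1) * (I_b(z+1, N-z+1) - I_a(z+1, N-z+1))
  lp_hi <- stats::pbeta(b, z + 1, N - z + 1, log.p = TRUE)
  lp_lo <- stats::pbeta(a, z + 1, N - z + 1, log.p = TRUE)
  log_mass <- lp_hi + log1p(-exp(lp_lo - lp_hi))
  log_int <- lbeta(z + 1, N - z + 1) + log_mass
  log_alt <- log_int - log(b - a)
  log_null <- z * log(t0) + (N - z) * log1p(-t0)
  log_alt - log_null
}

#' Group log Bayes factor
#'
#' Animals are independent, so the group Bayes factor is the product of the
#' per-animal factors, i.e. the sum of their natural logs.
#'
#' @param log_bfs Nonempty numeric vector of finite per-animal log BFs.
#' @return Sum of the inputs.
#' @export
group_bayes_factor <- function(log_bfs) {
  if (length(log_bfs) == 0L) {
    stop("need at least one per-animal log Bayes factor", call. = FALSE)
  }
  if (any(!is.finite(log_bfs))) {
    stop("log Bayes factors must be finite", call. = FALSE)
  }
  sum(log_bfs)
}

#' Evidence decision from a log Bayes factor
#'
#' Conventional substantial-evidence thresholds: alternative when
#' log(BF) > ln 3, null when log(BF) < ln(1/3), otherwise inconclusive.
#' The exact ln 3 is used, not the rounded 1.1.
#'
#' @param log_bf Finite numeric (vectorised).
#' @return Character vector in {"alt", "null", "inconclusive"}.
#' @export
bf_decision <- function(log_bf) {
  if (any(!is.finite(log_bf))) {
    stop("log_bf must be finite", call. = FALSE)
  }
  ifelse(log_bf > log(3), "alt",
         ifelse(log_bf < -log(3), "null", "inconclusive"))
}

#' Per-animal and group Bayes factors for a set of trial records
#'
#' Scores each animal's dig outcomes under the C/G model (success = first
#' dig on the rewarded axis, i.e. in {C, G}) or the C model (success =
#' first dig exactly C, contexts pooled), then aggregates.
#'
#' @param trials Data frame with columns `animal`, `dig1` (and optionally
#'   a filtering column `context`).
#' @param model "cg" or "c".
#' @return List with `per_animal` (data.frame: animal, z, N, log_bf,
#'   decision), `log_bf_group` and `group_decision`.
#' @export
behavior_bayes_factors <- function(trials, model = c("cg", "c")) {
  model <- match.arg(model)
  stopifnot("animal" %in% names(trials))
  success <- if (model == "cg") {
    trials$dig1 %in% c("C", "G")
  } else {
    trials$dig1 == "C"
  }
  keep <- !is.na(trials$dig1)
  per <- do.call(rbind, lapply(split(seq_len(nrow(trials))[keep],
                                     trials$animal[keep]), function(idx) {
    z <- sum(success[idx]); N <- length(idx)
    lbf <- bayes_factor(bernoulli_dig_model(z, N, model))
    data.frame(animal = trials$animal[idx[1]], z = z, N = N, log_bf = lbf)
  }))
  rownames(per) <- NULL
  per$decision <- bf_decision(per$log_bf)
  grp <- group_bayes_factor(per$log_bf)
  list(per_animal = per, log_bf_group = grp,
       group_decision = bf_decision(grp))
}
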