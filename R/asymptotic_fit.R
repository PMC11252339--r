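#' Fit an asymptotic regression to a Corr-Decile series
#'
#' Nonlinear least squares for \eqn{y(x) = a - (a - b) e^{-c x}} with
#' \eqn{c > 0} (asymptote `a`, value at x = 0 `b`, rate `c`), fit by
#' Levenberg-Marquardt from 16 deterministic starts over a log-spaced rate
#' grid (seed-free). Reports Gaussian log-likelihood,
#' AIC = 2k - 2 logLik with k = 4 (three curve parameters plus the noise
#' variance), residual standard error, and closed-form curve features:
#' half-life ln2/c, the root solving y = 0 (when `a` and `b` have opposite
#' signs), and the maximal-relative-growth locus (the left edge of the
#' positive domain, where y'/y peaks, since y'/y is decreasing on y > 0).
#'
#' @param x Predictor (decile index 1-10 in the threshold analysis).
#' @param y Response (per-decile within/across Pearson R). `NA` points are
#'   dropped; at least 4 defined points are required.
#' @return An `asymptotic_fit`: list with `a`, `b`, `c`, `fitted`,
#'   `residuals`, `rss`, `logLik`, `AIC`, `RSE`, `half_life`, `root`
#'   (`NA` when it does not exist), `max_growth_x`, `converged`.
#'   Non-convergence from every start yields `converged = FALSE` with all
#'   parameters `NA` (no silent fallback).
#' @export
fit_asymptotic_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) {
    stop("need at least 4 defined points", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("degenerate series: response is constant, rate is unidentifiable",
         call. = FALSE)
  }
  n <- length(x)
  c_grid <- exp(seq(log(0.02), log(5), length.out = 16))
  best <- NULL
  for (c0 in c_grid) {
    st <- list(a = y[which.max(x)], b = 2 * y[which.min(x)] -
                 y[which.max(x)], cc = c0)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a - (a - b) * exp(-cc * x),
                        start = st,
                        lower = c(a = -Inf, b = -Inf, cc = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                          fitted = rep(NA_real_, n),
                          residuals = rep(NA_real_, n), rss = NA_real_,
                          logLik = NA_real_, AIC = NA_real_,
                          RSE = NA_real_, half_life = NA_real_,
                          root = NA_real_, max_growth_x = NA_real_,
                          converged = FALSE),
                     class = "asymptotic_fit"))
  }
  cf <- stats::coef(best$fit)
  a <- cf[["a"]]; b <- cf[["b"]]; cc <- cf[["cc"]]
  rss <- best$rss
  sigma2 <- rss / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- 4
  aic <- 2 * k - 2 * ll
  rse <- sqrt(rss / (n - 3))
  half_life <- log(2) / cc
  ratio <- a / (a - b)
  root <- if (sign(a) != sign(b) && ratio > 0) -log(ratio) / cc
          else NA_real_
  max_growth_x <- if (is.na(root)) min(x) else max(root, min(x))
  structure(list(a = a, b = b, c = cc,
                 fitted = stats::fitted(best$fit),
                 residuals = stats::resid(best$fit), rss = rss,
                 logLik = ll, AIC = aic, RSE = rse,
                 half_life = half_life, root = root,
                 max_growth_x = max_growth_x, converged = TRUE),
            class = "asymptotic_fit")
}

#' Predict from an asymptotic fit
#' @param object An `asymptotic_fit`.
#' @param x Predictor values.
#' @param ... Ignored.
#' @return Fitted y values.
#' @export
predict_asymptotic <- function(object, x, ...) {
  stopifnot(inherits(object, "asymptotic_fit"), object$converged)
  object$a - (object$a - object$b) * exp(-object$c * x)
}

#' Select the FS/FI similarity threshold from a fitted decile curve
#'
#' The selected decile is the one containing the fitted curve's half-life,
#' root and maximal-relative-growth locus (the lowest decile consistent
#' with all available features when they coincide; each feature's decile
#' is reported otherwise). The threshold is the empirical upper score
#' boundary of that decile. When the root does not exist the selection
#' falls back on half-life and growth, flagged.
#'
#' @param fit An `asymptotic_fit` over decile indices 1-10.
#' @param decile_boundaries The 11 empirical score break points (from
#'   [within_across_decile_curve()]`$boundaries`).
#' @return List with `decile`, `threshold`, `feature_deciles` (named),
#'   `root_defined` and `unanimous`.
#' @export
select_threshold <- function(fit, decile_boundaries) {
  stopifnot(inherits(fit, "asymptotic_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  stopifnot(length(decile_boundaries) == 11L)
  to_decile <- function(v) {
    if (is.na(v)) return(NA_integer_)
    max(1L, min(10L, as.integer(ceiling(v))))
  }
  feats <- c(half_life = to_decile(fit$half_life),
             root = to_decile(fit$root),
             max_growth = to_decile(fit$max_growth_x))
  avail <- feats[!is.na(feats)]
  decile <- min(avail)
  list(decile = decile,
       threshold = unname(decile_boundaries[decile + 1L]),
       feature_deciles = feats,
       root_defined = !is.na(fit$root),
       unanimous = length(unique(avail)) == 1L)
}
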