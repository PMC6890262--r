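# Reverse inference: from a measured threshold distribution to the stimulus
# distribution it would optimally encode.
#
# Exponent bookkeeping (the one documented place for cumulative <-> density
# conversions): if the cumulative distribution of INVERSE thresholds follows
# P(1/theta > z) ~ z^(-lambda), then the density of 1/theta is ~ z^(-lambda-1)
# and the change of variables theta = 1/z gives a threshold density
# p(theta) ~ theta^(lambda-1). With lambda = 0.42 the threshold-density
# exponent is -0.58. Under infomax optimality the threshold density equals
# the stimulus density (x(theta) = int p), so the stimulus exponent is the
# same; under minimal linear-readout MSE it equals the one-third power
# (x(theta) = int p^(1/3)), so the stimulus exponent is tripled.

#' Fit a power law to a set of activation thresholds
#'
#' Fits the cumulative distribution of inverse thresholds on log-log axes by
#' ordinary least squares, the standard presentation for pooled dose-response
#' thresholds. Reports the cumulative slope (`-lambda`), the implied
#' threshold-density exponent (`lambda - 1`), the empirical upper cutoff, and
#' a maximum-likelihood truncated-Pareto exponent as a cross-check (OLS is
#' the reported value).
#'
#' @param thresholds positive thresholds (>= 20 values).
#' @param survival_range survival probabilities included in the OLS fit;
#'   trimming the extremes avoids the curvature induced by the finite cutoffs.
#' @return object of class `powerlaw_fit` with `slope` (cumulative log-log
#'   slope, \eqn{-\lambda}), `lambda`, `density_exponent`
#'   (\eqn{\lambda - 1}), `cutoff`, `r_squared`, `mle_lambda`, `degenerate`.
#' @export
fit_threshold_powerlaw <- function(thresholds, survival_range = c(0.3, 0.99)) {
  thresholds <- as.numeric(thresholds)
  if (any(!is.finite(thresholds) | thresholds <= 0))
    stop("thresholds must be positive and finite")
  n <- length(thresholds)
  if (n < 20) stop("at least 20 thresholds required")
  z <- sort(1 / thresholds)
  if (max(z) / min(z) < 1 + 1e-10) {
    out <- list(slope = NA_real_, lambda = NA_real_,
                density_exponent = NA_real_, cutoff = max(thresholds),
                r_squared = NA_real_, mle_lambda = NA_real_,
                degenerate = TRUE, n = n)
    return(structure(out, class = "powerlaw_fit"))
  }
  surv <- (n - seq_len(n)) / n            # P(Z > z_(i))
  keep <- surv >= survival_range[1] & surv <= survival_range[2] & z > 0
  fit <- stats::lm(log(surv[keep]) ~ log(z[keep]))
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  lambda <- -slope
  # ML cross-check: truncated Pareto for z on (zlo, zhi), density ~ z^(-lambda-1)
  zlo <- min(z); zhi <- max(z)
  mle <- tryCatch({
    nll <- function(lam) {
      if (abs(lam) < 1e-9) return(n * log(log(zhi / zlo)) + sum(log(z)))
      k <- lam / (zlo^(-lam) - zhi^(-lam))
      -sum(log(k) - (lam + 1) * log(z))
    }
    stats::optimize(nll, c(-5, 5))$minimum
  }, error = function(e) NA_real_)
  structure(list(slope = slope, lambda = lambda,
                 density_exponent = lambda - 1,
                 cutoff = max(thresholds), r_squared = r2,
                 mle_lambda = mle, degenerate = FALSE, n = n),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Power-law fit: degenerate input (all thresholds equal); ",
        "no exponent estimated\n")
    return(invisible(x))
  }
  cat(sprintf("Power-law threshold fit (n = %d)\n", x$n))
  cat(sprintf("  cumulative slope of inverse thresholds: %.4g (R^2 = %.4f)\n",
              x$slope, x$r_squared))
  cat(sprintf("  threshold-density exponent: %.4g  (ML cross-check lambda: %.4g)\n",
              x$density_exponent, x$mle_lambda))
  cat(sprintf("  upper cutoff: %.4g\n", x$cutoff))
  invisible(x)
}

#' Predicted stimulus-distribution exponent under an optimality criterion
#'
#' Given the exponent of a power-law threshold density, returns the exponent
#' of the power-law stimulus (e.g. odorant concentration) distribution the
#' thresholds would optimally encode. Under infomax, thresholds equalize the
#' stimulus mass, so the stimulus density has the same exponent; under the
#' minimal-MSE linear readout, thresholds equalize the mass of the one-third
#' power of the density, so the exponent is tripled. A threshold-density
#' exponent of -0.58 thus predicts -0.58 (infomax) or -1.74 (linear MSE).
#'
#' @param density_exponent threshold-density exponent (e.g. from
#'   [fit_threshold_powerlaw()]).
#' @param criterion `"infomax"` or `"linear_mse"`.
#' @return predicted stimulus-density exponent.
#' @export
infer_stimulus_distribution <- function(density_exponent,
                                        criterion = c("infomax", "linear_mse")) {
  criterion <- match.arg(criterion)
  if (!is.finite(density_exponent)) stop("exponent must come from a valid fit")
  switch(criterion,
         infomax = density_exponent,
         linear_mse = 3 * density_exponent)
}
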