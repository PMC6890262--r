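#' Optimal linear readout of an ON/OFF population
#'
#' Fits the decoding weights, offset and firing thresholds that minimize the
#' mean squared error of the linear stimulus estimate
#' \eqn{y = R^{-1}\sum_i w_i n_i + w_0} read from the Poisson spike counts
#' `n_i` of `N` binary ON/OFF neurons (noiseless limit: \eqn{y = \sum_i w_i
#' a_i(s) + w_0} with deterministic activations).
#'
#' Without noise (`R = Inf`) the solution is the Lloyd-Max fixed point:
#' weights are differences of interval centers of mass, thresholds are
#' midpoints of neighboring centers, the MSE is the within-interval variance,
#' and the optimum is identical for every ON/OFF mixture (only the offset
#' changes). With noise the normal equations acquire a diagonal Poisson
#' penalty and the threshold stationarity picks up a `w_i/(2R)` shift; the
#' solver alternates exact weight/offset solves with damped threshold updates
#' until the MSE stabilizes.
#'
#' @param dist a [stimulus_distribution()].
#' @param N population size.
#' @param m number of ON cells; the `N - m` OFF cells take the lower
#'   thresholds (non-overlapping configuration).
#' @param R expected spike count per active neuron; `Inf` for the noiseless
#'   limit.
#' @param tol relative MSE convergence tolerance.
#' @param max_iter iteration cap.
#' @return object of class `linear_readout` with elements `theta` (sorted
#'   thresholds), `weights`, `w0`, `labels`, `mse`, `iterations`,
#'   `converged`, `trace` (MSE per iteration), `dist`, `R`.
#' @examples
#' d <- stimulus_distribution("uniform", min = 0, max = 1)
#' linear_readout(d, N = 1, m = 1) # theta = 1/2, w0 = 1/4, MSE = 1/48
#' @export
linear_readout <- function(dist, N, m = N, R = Inf, tol = 1e-10,
                           max_iter = 10000) {
  stopifnot(N >= 1, m >= 0, m <= N, R > 0)
  if (is.infinite(R)) .solve_noiseless(dist, N, m, tol, max_iter)
  else .solve_with_noise(dist, N, m, R, tol, max_iter)
}

.readout_labels <- function(N, m) c(rep("F", N - m), rep("N", m))

# ---- noiseless Lloyd-Max alternation -------------------------------------

.solve_noiseless <- function(dist, N, m, tol = 1e-10, max_iter = 10000) {
  # thresholds are mixture-independent; solve the homogeneous quantizer
  theta <- qstim(dist, seq_len(N) / (N + 1))
  mo <- stim_moments(dist)
  slo <- dist$support[1]; shi <- dist$support[2]
  quantizer_state <- function(theta) {
    lo <- c(slo, theta); hi <- c(theta, shi)
    pm <- stim_partial_moments(dist, lo, hi)
    list(pm = pm, centers = pm$m1 / pm$m0,
         # summed within-interval variances: avoids cancellation at large N
         mse = sum(pmax(pm$m2 - pm$m1^2 / pm$m0, 0)))
  }
  trace <- numeric(0)
  mse_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    st <- quantizer_state(theta)
    trace <- c(trace, st$mse)
    if (st$mse > mse_old + 1e-8 * abs(mse_old))
      warning("Lloyd iteration increased the MSE; numerical precision limit")
    if (is.finite(mse_old) && abs(mse_old - st$mse) <= tol * max(st$mse, 1e-300)) {
      converged <- TRUE
      mse_old <- st$mse
      break
    }
    mse_old <- st$mse
    theta_lloyd <- (st$centers[-1] + st$centers[-(N + 1)]) / 2
    # Lloyd alternation is only linearly convergent (rate -> 1 for large N);
    # after a stabilizing burn-in, polish with Newton on the stationarity
    # conditions F_i = theta_i - (c_i + c_{i-1})/2 (tridiagonal Jacobian)
    theta_new <- theta_lloyd
    if (it > 10) {
      nw <- .quantizer_newton_step(dist, theta, st)
      if (!is.null(nw)) {
        st_nw <- quantizer_state(nw)
        if (st_nw$mse <= quantizer_state(theta_lloyd)$mse) theta_new <- nw
      }
    }
    theta <- theta_new
  }
  st <- quantizer_state(theta)
  mse_old <- st$mse
  centers <- st$centers
  w_hom <- diff(centers)                     # homogeneous ON weights
  labels <- .readout_labels(N, m)
  weights <- ifelse(labels == "N", w_hom, -w_hom)
  w0 <- centers[N - m + 1]                   # center of the uncoded interval
  structure(list(theta = theta, weights = weights, w0 = w0, labels = labels,
                 mse = mse_old, iterations = length(trace),
                 converged = converged, trace = trace, dist = dist, R = Inf,
                 N = N, m = m),
            class = "linear_readout")
}

# one Newton step on the quantizer stationarity conditions; returns NULL if
# the step leaves the feasible (sorted) region
.quantizer_newton_step <- function(dist, theta, st) {
  N <- length(theta)
  cts <- st$centers; m0 <- st$pm$m0
  p <- dstim(dist, theta)
  Fv <- theta - (cts[-1] + cts[-(N + 1)]) / 2
  # derivatives of the interval centers of mass w.r.t. their endpoints
  dc_lo <- p * (cts[-1] - theta) / m0[-1]        # d c_i / d theta_i
  dc_hi <- p * (theta - cts[-(N + 1)]) / m0[-(N + 1)]  # d c_{i-1} / d theta_i
  diag_main <- 1 - 0.5 * (dc_lo + dc_hi)
  J <- diag(diag_main, N)
  if (N > 1) {
    up <- -0.5 * p[-1] * (theta[-1] - cts[2:N]) / m0[2:N]
    lo <- -0.5 * p[-N] * (cts[2:N] - theta[-N]) / m0[2:N]
    J[cbind(seq_len(N - 1), 2:N)] <- up
    J[cbind(2:N, seq_len(N - 1))] <- lo
  }
  step <- tryCatch(solve(J, Fv), error = function(e) NULL)
  if (is.null(step)) return(NULL)
  cand <- theta - step
  if (is.unsorted(cand)) return(NULL)
  if (is.finite(dist$support[1]) && cand[1] <= dist$support[1]) return(NULL)
  if (is.finite(dist$support[2]) && cand[N] >= dist$support[2]) return(NULL)
  cand
}

# ---- analytic MSE for an arbitrary readout -------------------------------

#' Analytic mean squared error of a linear readout
#'
#' Evaluates the exact MSE of an arbitrary (not necessarily optimal) linear
#' readout of binary ON/OFF Poisson responses,
#' \deqn{E = w^T C w - 2 U^T w + \langle (s - w_0)^2 \rangle,}
#' with activation covariance \eqn{C_{ij} = \langle a_i a_j\rangle +
#' \delta_{ij}\langle a_i\rangle / R} and \eqn{U_i = \langle s a_i\rangle -
#' w_0 \langle a_i \rangle}. The full cross-covariance is used, so
#' overlapping ON/OFF response regions are handled exactly; `R = Inf`
#' recovers the noiseless quadratic form.
#'
#' @param readout a `linear_readout` object, or a list with `theta`,
#'   `weights`, `w0`, `labels`.
#' @param dist stimulus distribution (defaults to the readout's own).
#' @param R noise level (defaults to the readout's own).
#' @return the mean squared error (stimulus units squared).
#' @export
evaluate_mse <- function(readout, dist = NULL, R = NULL) {
  dist <- dist %||% readout$dist
  R <- R %||% readout$R
  th <- readout$theta; w <- readout$weights; w0 <- readout$w0
  on <- readout$labels == "N"
  mo <- stim_moments(dist)
  if (length(th) == 0)
    return(mo$second_moment - 2 * w0 * mo$mean + w0^2)
  x <- pstim(dist, th)
  a_mean <- ifelse(on, 1 - x, x)
  N <- length(th)
  AA <- .overlap_matrix(x, on)
  pm_up <- stim_partial_moments(dist, th, rep(dist$support[2], N))
  pm_dn <- stim_partial_moments(dist, rep(dist$support[1], N), th)
  s_a <- ifelse(on, pm_up$m1, pm_dn$m1)
  noise <- if (is.infinite(R)) 0 else sum(w^2 * a_mean) / R
  drop(t(w) %*% AA %*% w) + noise +
    2 * w0 * sum(w * a_mean) - 2 * sum(w * s_a) +
    mo$second_moment - 2 * w0 * mo$mean + w0^2
}

# ---- noisy solver --------------------------------------------------------

.solve_with_noise <- function(dist, N, m, R, tol = 1e-10, max_iter = 10000) {
  labels <- .readout_labels(N, m)
  on <- labels == "N"
  mo <- stim_moments(dist)
  # infomax equal-mass profile as the starting ansatz
  x0 <- optimal_thresholds(N, m, R = R, dist = dist)$x
  theta <- qstim(dist, pmin(pmax(x0, 1e-9), 1 - 1e-9))
  solve_weights <- function(theta) {
    x <- pstim(dist, theta)
    a_mean <- ifelse(on, 1 - x, x)
    M <- .overlap_matrix(x, on) + diag(a_mean, N) / R
    pm_up <- stim_partial_moments(dist, theta, rep(dist$support[2], N))
    pm_dn <- stim_partial_moments(dist, rep(dist$support[1], N), theta)
    s_a <- ifelse(on, pm_up$m1, pm_dn$m1)
    A <- rbind(c(1, a_mean), cbind(a_mean, M))
    b <- c(mo$mean, s_a)
    sol <- tryCatch(solve(A, b), error = function(e) {
      solve(A + diag(1e-10, N + 1), b)
    })
    list(w0 = unname(sol[1]), w = unname(sol[-1]), a_mean = a_mean,
         M = M, s_a = s_a)
  }
  mse_at <- function(theta, w0, w) {
    evaluate_mse(list(theta = theta, weights = w, w0 = w0, labels = labels,
                      dist = dist, R = R), dist, R)
  }
  sol <- solve_weights(theta)
  mse_old <- mse_at(theta, sol$w0, sol$w)
  trace <- mse_old
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # decoder value on each of the N + 1 intervals
    f <- .interval_values(sol$w0, sol$w, on)
    prop <- (f[-1] + f[-(N + 1)]) / 2 + sol$w / (2 * R)
    prop <- sort(prop)
    # keep thresholds inside the support for bounded distributions
    eps <- 1e-9
    lohi <- dist$support
    if (is.finite(lohi[1])) prop <- pmax(prop, lohi[1] + eps)
    if (is.finite(lohi[2])) prop <- pmin(prop, lohi[2] - eps)
    prop <- .separate(prop, 1e-12)
    step <- 1
    repeat {
      theta_new <- sort(theta + step * (prop - theta))
      sol_new <- solve_weights(theta_new)
      mse_new <- mse_at(theta_new, sol_new$w0, sol_new$w)
      if (mse_new <= mse_old + 1e-14 * abs(mse_old) || step < 1e-6) break
      step <- step / 2                      # damped update
    }
    theta <- theta_new; sol <- sol_new
    trace <- c(trace, mse_new)
    if (abs(mse_old - mse_new) <= tol * max(abs(mse_new), 1e-300)) {
      converged <- TRUE
      mse_old <- mse_new
      break
    }
    mse_old <- mse_new
  }
  structure(list(theta = theta, weights = sol$w, w0 = sol$w0, labels = labels,
                 mse = mse_old, iterations = length(trace) - 1,
                 converged = converged, trace = trace, dist = dist, R = R,
                 N = N, m = m),
            class = "linear_readout")
}

# pairwise masses <a_i a_j> of joint activation for thresholds at cumulative
# positions x with ON/OFF indicator `on`; exact for overlapping regions too
.overlap_matrix <- function(x, on) {
  N <- length(x)
  M <- matrix(0, N, N)
  if (any(on))
    M[on, on] <- 1 - outer(x[on], x[on], pmax)
  if (any(!on))
    M[!on, !on] <- outer(x[!on], x[!on], pmin)
  if (any(on) && any(!on)) {
    cross <- outer(x[!on], x[on], function(a, b) pmax(a - b, 0))
    M[!on, on] <- cross
    M[on, !on] <- t(cross)
  }
  M
}

# decoder output on intervals 0..N given sorted thresholds with labels
.interval_values <- function(w0, w, on) {
  N <- length(w)
  vapply(0:N, function(k) {
    w0 + sum(w[on & seq_len(N) <= k]) + sum(w[!on & seq_len(N) > k])
  }, 0)
}

.separate <- function(v, eps) {
  if (length(v) > 1) for (i in 2:length(v))
    if (v[i] - v[i - 1] < eps) v[i] <- v[i - 1] + eps
  v
}

#' @export
print.linear_readout <- function(x, ...) {
  cat(sprintf("Optimal linear readout: N = %d (%d ON / %d OFF), R = %s\n",
              x$N, x$m, x$N - x$m,
              if (is.infinite(x$R)) "Inf (noiseless)" else format(x$R)))
  cat(sprintf("  MSE = %.6g  (%d iterations%s)\n", x$mse, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  cat("  w0 =", signif(x$w0, 6), "\n")
  if (x$N <= 12) {
    cat("  thresholds:", paste(signif(x$theta, 4), collapse = " "), "\n")
    cat("  weights:   ", paste(signif(x$weights, 4), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
coef.linear_readout <- function(object, ...) {
  c(w0 = object$w0,
    stats::setNames(object$weights, paste0("w", seq_along(object$weights))))
}

#' Decode stimuli from spike counts
#'
#' Applies the linear decoder \eqn{y = R^{-1} \sum w_i n_i + w_0} to a matrix
#' of spike counts (trials by neurons), or, when `counts` is omitted and
#' stimulus values are given, returns the deterministic decoder output
#' \eqn{\sum w_i a_i(s) + w_0}.
#'
#' @param object a `linear_readout`.
#' @param counts integer matrix of spike counts (trials x neurons).
#' @param s stimulus values (used when `counts` is missing).
#' @param ... unused.
#' @return numeric vector of stimulus estimates.
#' @export
predict.linear_readout <- function(object, counts = NULL, s = NULL, ...) {
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    scale <- if (is.infinite(object$R)) 1 else 1 / object$R
    drop(counts %*% (object$weights * scale)) + object$w0
  } else if (!is.null(s)) {
    on <- object$labels == "N"
    act <- outer(s, object$theta, ">=")
    act[, !on] <- !act[, !on, drop = FALSE]
    drop(act %*% object$weights) + object$w0
  } else stop("supply 'counts' or 's'")
}

#' @export
residuals.linear_readout <- function(object, s, ...) {
  predict(object, s = s) - s
}

#' @export
plot.linear_readout <- function(x, n_grid = 400, ...) {
  rng <- qstim(x$dist, c(0.001, 0.999))
  s <- seq(rng[1], rng[2], length.out = n_grid)
  graphics::plot(s, predict(x, s = s), type = "l",
                 xlab = "stimulus s", ylab = "decoded estimate", ...)
  graphics::abline(0, 1, lty = 3)
  graphics::rug(x$theta)
  invisible(x)
}

#' @export
simulate.linear_readout <- function(object, nsim = 1, seed = NULL, ...) {
  prof <- threshold_profile(pstim(object$dist, object$theta), object$labels,
                            object$dist)
  s <- qstim(object$dist, stats::runif(nsim))
  simulate_responses(prof, R = if (is.finite(object$R)) object$R else 1e6,
                     stimuli = s, seed = seed)
}

# ---- OFF-fraction sweep --------------------------------------------------

#' MSE of the optimal linear readout as a function of the OFF fraction
#'
#' Runs [linear_readout()] for each OFF fraction on a grid, normalizes the
#' MSE to the homogeneous all-ON population (`alpha = 0`), and locates the
#' best mixture. Grid values are mapped to integer ON counts
#' `m = round((1 - alpha) N)`; the reported `alpha` is the one realized by
#' `m`, not the requested grid value.
#'
#' @inheritParams linear_readout
#' @param alpha numeric grid of OFF fractions in `[0, 1]`.
#' @return object of class `mse_curve`: data frame `curve` (columns `alpha`,
#'   `m`, `mse`, `mse_normalized`, `converged`) plus `alpha_opt`.
#' @export
sweep_off_fraction <- function(dist, N, R, alpha = seq(0, 1, by = 0.1),
                               tol = 1e-10, max_iter = 10000) {
  m <- unique(round((1 - alpha) * N))
  m <- sort(union(m, N), decreasing = TRUE)    # always include alpha = 0
  fits <- lapply(m, function(mm)
    linear_readout(dist, N, mm, R, tol = tol, max_iter = max_iter))
  mse <- vapply(fits, `[[`, 0, "mse")
  conv <- vapply(fits, `[[`, TRUE, "converged")
  curve <- data.frame(alpha = (N - m) / N, m = m, mse = mse,
                      mse_normalized = mse / mse[1], converged = conv)
  structure(list(curve = curve,
                 alpha_opt = curve$alpha[which.min(curve$mse)],
                 N = N, R = R, dist = dist),
            class = "mse_curve")
}

#' @export
print.mse_curve <- function(x, ...) {
  cat(sprintf("MSE vs OFF fraction: N = %d, R = %s; optimal alpha = %.3g\n",
              x$N, format(x$R), x$alpha_opt))
  print(x$curve, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.mse_curve <- function(x, ...) {
  graphics::plot(x$curve$alpha, x$curve$mse_normalized, type = "b",
                 xlab = "OFF fraction alpha", ylab = "MSE / MSE(alpha = 0)",
                 ...)
  graphics::abline(v = x$alpha_opt, lty = 3)
  invisible(x)
}
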