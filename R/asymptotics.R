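# Large-population threshold laws for Laplace-family stimulus distributions.
#
# In the large-N limit the optimal-readout thresholds admit closed or
# semi-closed forms. Without noise the threshold function is the compressed
# (one-third power) quantile. With noise, the local stationarity conditions of
# the analytic MSE give a threshold density proportional to sqrt(T(theta))
# below the mode (T = mass of the response region) and to
# sqrt(A+ tau+) e^{-theta/(2 tau+)} in the upper tail, anchored by a first
# threshold theta_1; for mixed populations the ON and OFF branches meet at a
# common first threshold phi(X) fixed by the offset stationarity,
# w_ON T(phi) = w_OFF F(phi). The derivation is laid out in the methods
# vignette and validated against the full numerical solver.

# Laplace-family parameters in a common form
.lap_params <- function(dist) {
  if (dist$family == "laplace") {
    if (dist$params$mu != 0)
      stop("asymptotic threshold laws assume a distribution centered at 0")
    tau <- dist$params$tau
    list(Ap = 1 / (2 * tau), Am = 1 / (2 * tau), tp = tau, tm = tau)
  } else if (dist$family == "asymmetric_laplace") {
    p <- dist$params
    list(Ap = p$A_plus, Am = p$A_minus, tp = p$tau_plus, tm = p$tau_minus)
  } else {
    stop("asymptotic threshold laws are available for Laplace-family ",
         "distributions only; use the numerical solver linear_readout()")
  }
}

# antiderivative of sqrt(1 - Am tm e^{u/tm}) for u <= 0
.psi <- function(u, lp) {
  v <- sqrt(pmax(1 - lp$Am * lp$tm * exp(u / lp$tm), 0))
  2 * lp$tm * (v - atanh(pmin(v, 1 - 1e-16)))
}

# integral of the bulk density from phi to 0
.bulk_mass <- function(phi, lp) .psi(0, lp) - .psi(phi, lp)

# upper-tail density constant: integral over (0, Inf) of sqrt(A+ tau+) e^{-u/2tp}
.tail_mass <- function(lp) 2 * lp$tp * sqrt(lp$Ap * lp$tp)

#' First threshold of the mixed-population noisy linear readout
#'
#' For a large mixed population with OFF-to-ON fraction ratio
#' `X = f_OFF / f_ON` (0 < X <= 1) decoding a Laplace-family stimulus, the
#' first ON and OFF thresholds coincide at a value \eqn{\phi \le 0} fixed by
#' the scalar equation
#' \deqn{X(\phi) = \frac{2\tau_- F(\phi)}{\sqrt{T(\phi)}\,
#'   [\int_\phi^0 \sqrt{T(u)}\,du + 2\tau_+\sqrt{A_+\tau_+}]},}
#' where \eqn{F} is the stimulus cdf and \eqn{T = 1 - F}. `X = 1` (equal
#' mixture) gives \eqn{\phi \approx 0}; for the symmetric Laplace,
#' `X = 1/4` gives \eqn{\phi = -0.79}.
#'
#' @param X OFF-to-ON fraction ratio in (0, 1].
#' @param dist Laplace-family [stimulus_distribution()].
#' @return the first threshold \eqn{\phi} (stimulus units).
#' @export
first_threshold_mixed <- function(X, dist = stimulus_distribution("laplace")) {
  if (X <= 0 || X > 1)
    stop("X = f_OFF/f_ON must lie in (0, 1] (population with at least as ",
         "many ON as OFF cells)")
  lp <- .lap_params(dist)
  Xfun <- function(phi) {
    Fm <- lp$Am * lp$tm * exp(phi / lp$tm)
    Tm <- 1 - Fm
    2 * lp$tm * Fm / (sqrt(Tm) * (.bulk_mass(phi, lp) + .tail_mass(lp)))
  }
  lo <- -50 * lp$tm
  if (Xfun(lo) > X || Xfun(0) < X - 1e-12)
    stop(sprintf("no bracketing root: X(phi) ranges over [%.3g, %.3g]",
                 Xfun(lo), Xfun(0)))
  if (X >= Xfun(0)) return(0)
  stats::uniroot(function(p) Xfun(p) - X, c(lo, 0), tol = 1e-12)$root
}

#' Asymptotic (large-N) optimal-readout threshold function
#'
#' Returns the threshold allocation \eqn{\theta(x)} on the population index
#' `x` in (0, 1) predicted by the large-population asymptotics of the
#' MSE-optimal linear readout for Laplace-family stimulus distributions.
#'
#' Noiseless (`R = Inf`): \eqn{\theta(x)} is the compressed quantile
#' [qstim_compressed()] — for the symmetric Laplace,
#' \eqn{3\log(2x)} for \eqn{x \le 1/2} and \eqn{-3\log(2(1-x))} above.
#' With noise, a homogeneous population has near-linear thresholds in the
#' bulk anchored at
#' \eqn{\theta_1 \approx \tau_- \log[\log(RN A_-\tau_-)/(RN A_-\tau_-^2)]}
#' with a logarithmic tail \eqn{\sim -2\tau_+ \log(1-x)}; a mixed population
#' splits at the common first threshold \eqn{\phi(X)} (see
#' [first_threshold_mixed()]), with OFF thresholds
#' \eqn{\theta(x) = \phi + 2\tau_-\log(x/f_{OFF})}.
#'
#' @inheritParams linear_readout
#' @return a vectorized function of the index `x` in (0, 1), with attributes
#'   `theta1` (first-threshold anchor) and, for mixed populations, `phi`.
#' @export
asymptotic_thresholds <- function(dist, N, m = N, R = Inf) {
  if (is.infinite(R)) {
    f <- function(x) qstim_compressed(dist, x)
    return(f)
  }
  lp <- .lap_params(dist)
  if (m == 0) {                      # all-OFF population: mirror symmetry
    mir <- stimulus_distribution("asymmetric_laplace",
                                 A_plus = lp$Am, A_minus = lp$Ap,
                                 tau_plus = lp$tm, tau_minus = lp$tp)
    g <- asymptotic_thresholds(mir, N, N, R)
    f <- function(x) -g(1 - x)
    attr(f, "theta1") <- -attr(g, "theta1")
    return(f)
  }
  f_on <- m / N; f_off <- 1 - f_on
  if (m == N) {
    # homogeneous: first threshold from the self-consistency
    # F(theta1) tau- = w1 / R, w1 = (bulk+tail mass)/(N sqrt(T(theta1)))
    gfun <- function(t1) {
      lhs <- lp$Am * lp$tm * exp(t1 / lp$tm) * lp$tm
      rhs <- (.bulk_mass(t1, lp) + .tail_mass(lp)) /
        (R * N * sqrt(1 - lp$Am * lp$tm * exp(t1 / lp$tm)))
      lhs - rhs
    }
    lo <- -50 * lp$tm
    if (gfun(lo) > 0 || gfun(0) < 0)
      stop("no asymptotic first threshold in range; RN too small for the ",
           "large-population regime")
    anchor <- stats::uniroot(gfun, c(lo, 0), tol = 1e-12)$root
  } else {
    if (f_off > f_on)
      stop("mixed asymptotics implemented for populations with at least as ",
           "many ON as OFF cells (m >= N/2)")
    anchor <- first_threshold_mixed(f_off / f_on, dist)
  }
  D <- .bulk_mass(anchor, lp) + .tail_mass(lp)
  psi_anchor <- .psi(anchor, lp)
  x_at_zero <- f_off + f_on * .bulk_mass(anchor, lp) / D
  invert_on <- function(xi) {
    # xi in (f_off, 1): ON branch
    target <- (xi - f_off) / f_on * D
    if (xi <= x_at_zero) {
      stats::uniroot(function(t) .psi(t, lp) - psi_anchor - target,
                     c(anchor, 0), tol = 1e-12)$root
    } else {
      rem <- target - .bulk_mass(anchor, lp)
      -2 * lp$tp * log(pmax(1 - rem / .tail_mass(lp), 1e-300))
    }
  }
  f <- function(x) {
    stopifnot(all(x > 0 & x < 1))
    vapply(x, function(xi) {
      if (xi <= f_off) anchor + 2 * lp$tm * log(xi / f_off)
      else invert_on(xi)
    }, 0)
  }
  attr(f, "theta1") <- anchor
  if (f_off > 0) attr(f, "phi") <- anchor
  f
}
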