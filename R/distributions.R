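#' Parametric one-dimensional stimulus distributions
#'
#' Constructs a stimulus distribution object used throughout the package.
#' Supported families:
#' \describe{
#'   \item{`"laplace"`}{symmetric Laplace \eqn{p(s) = e^{-|s-mu|/tau}/(2 tau)};
#'     parameters `mu` (default 0) and `tau` (default 1).}
#'   \item{`"asymmetric_laplace"`}{two exponential flanks
#'     \eqn{p(s) = A_+ e^{-s/\tau_+}} for \eqn{s \ge 0} and
#'     \eqn{p(s) = A_- e^{s/\tau_-}} for \eqn{s < 0}; parameters `tau_plus`,
#'     `tau_minus` and optionally `A_plus`, `A_minus`. If amplitudes are
#'     omitted the density is taken continuous at 0,
#'     \eqn{A_+ = A_- = 1/(\tau_+ + \tau_-)}. Normalization
#'     \eqn{A_+\tau_+ + A_-\tau_- = 1} is enforced.}
#'   \item{`"uniform"`}{uniform on `[min, max]` (defaults 0, 1).}
#'   \item{`"truncated_power_law"`}{\eqn{p(s) \propto s^{exponent}} on
#'     `[lower, upper]`, both cutoffs finite and positive.}
#'   \item{`"gaussian"`}{normal with `mean` (0) and `sd` (1); included as a
#'     convenience family for testing distribution-independence claims.}
#' }
#'
#' @param family character, one of the families above.
#' @param ... family-specific parameters, see Details.
#' @return An object of class `stim_dist` with elements `family`, `params`
#'   and `support`.
#' @examples
#' d <- stimulus_distribution("laplace")
#' qstim(d, 0.5)
#' @export
stimulus_distribution <- function(family = c("laplace", "asymmetric_laplace",
                                             "uniform", "truncated_power_law",
                                             "gaussian"), ...) {
  family <- match.arg(family)
  p <- list(...)
  params <- switch(family,
    laplace = {
      mu <- p$mu %||% 0; tau <- p$tau %||% 1
      stopifnot(tau > 0)
      list(mu = mu, tau = tau)
    },
    asymmetric_laplace = {
      tp <- p$tau_plus %||% 1; tm <- p$tau_minus %||% 1
      stopifnot(tp > 0, tm > 0)
      if (is.null(p$A_plus) && is.null(p$A_minus)) {
        Ap <- Am <- 1 / (tp + tm)
      } else {
        Ap <- p$A_plus; Am <- p$A_minus
        if (is.null(Am)) Am <- (1 - Ap * tp) / tm
        if (is.null(Ap)) Ap <- (1 - Am * tm) / tp
      }
      if (Ap < 0 || Am < 0 || abs(Ap * tp + Am * tm - 1) > 1e-8)
        stop("asymmetric Laplace amplitudes must satisfy A+ tau+ + A- tau- = 1")
      list(A_plus = Ap, A_minus = Am, tau_plus = tp, tau_minus = tm)
    },
    uniform = {
      lo <- p$min %||% 0; hi <- p$max %||% 1
      stopifnot(hi > lo)
      list(min = lo, max = hi)
    },
    truncated_power_law = {
      a <- p$exponent %||% -1
      lo <- p$lower %||% 1; hi <- p$upper %||% stop("'upper' cutoff required")
      stopifnot(lo > 0, hi > lo)
      list(exponent = a, lower = lo, upper = hi)
    },
    gaussian = {
      m <- p$mean %||% 0; s <- p$sd %||% 1
      stopifnot(s > 0)
      list(mean = m, sd = s)
    })
  support <- switch(family,
    laplace = c(-Inf, Inf),
    asymmetric_laplace = c(-Inf, Inf),
    uniform = c(params$min, params$max),
    truncated_power_law = c(params$lower, params$upper),
    gaussian = c(-Inf, Inf))
  structure(list(family = family, params = params, support = support),
            class = "stim_dist")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.stim_dist <- function(x, ...) {
  cat("Stimulus distribution:", x$family, "\n")
  cat("  parameters:",
      paste(names(x$params), signif(unlist(x$params), 6), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

# normalizing constant of the truncated power law
.tpl_const <- function(p) {
  a <- p$exponent
  if (abs(a + 1) < 1e-12) 1 / log(p$upper / p$lower)
  else (a + 1) / (p$upper^(a + 1) - p$lower^(a + 1))
}

#' Stimulus density
#'
#' @param dist a [stimulus_distribution()] object.
#' @param s numeric vector of stimulus values.
#' @return density values.
#' @export
dstim <- function(dist, s) {
  p <- dist$params
  switch(dist$family,
    laplace = exp(-abs(s - p$mu) / p$tau) / (2 * p$tau),
    asymmetric_laplace = ifelse(s >= 0, p$A_plus * exp(-s / p$tau_plus),
                                p$A_minus * exp(s / p$tau_minus)),
    uniform = stats::dunif(s, p$min, p$max),
    truncated_power_law = ifelse(s >= p$lower & s <= p$upper,
                                 .tpl_const(p) * s^p$exponent, 0),
    gaussian = stats::dnorm(s, p$mean, p$sd))
}

#' Stimulus cumulative distribution function
#'
#' @inheritParams dstim
#' @return cumulative probabilities \eqn{P(S \le s)}.
#' @export
pstim <- function(dist, s) {
  p <- dist$params
  switch(dist$family,
    laplace = {
      z <- (s - p$mu) / p$tau
      ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
    },
    asymmetric_laplace = ifelse(s < 0,
      p$A_minus * p$tau_minus * exp(s / p$tau_minus),
      1 - p$A_plus * p$tau_plus * exp(-s / p$tau_plus)),
    uniform = stats::punif(s, p$min, p$max),
    truncated_power_law = {
      k <- .tpl_const(p); a <- p$exponent
      s2 <- pmin(pmax(s, p$lower), p$upper)
      if (abs(a + 1) < 1e-12) k * log(s2 / p$lower)
      else k * (s2^(a + 1) - p$lower^(a + 1)) / (a + 1)
    },
    gaussian = stats::pnorm(s, p$mean, p$sd))
}

#' Stimulus quantile function
#'
#' Returns the stimulus value `s` with `pstim(dist, s) = x`. Closed form for
#' all built-in families except where numeric inversion (monotone bisection)
#' is required.
#'
#' @inheritParams dstim
#' @param x probabilities strictly inside (0, 1).
#' @return stimulus values.
#' @export
qstim <- function(dist, x) {
  if (any(x <= 0 | x >= 1)) stop("quantile argument must lie strictly in (0, 1)")
  p <- dist$params
  switch(dist$family,
    laplace = p$mu + p$tau * ifelse(x < 0.5, log(2 * x), -log(2 * (1 - x))),
    asymmetric_laplace = {
      Pm <- p$A_minus * p$tau_minus
      ifelse(x < Pm, p$tau_minus * log(x / Pm),
             -p$tau_plus * log((1 - x) / (p$A_plus * p$tau_plus)))
    },
    uniform = stats::qunif(x, p$min, p$max),
    truncated_power_law = {
      k <- .tpl_const(p); a <- p$exponent
      if (abs(a + 1) < 1e-12) p$lower * exp(x / k)
      else (x * (a + 1) / k + p$lower^(a + 1))^(1 / (a + 1))
    },
    gaussian = stats::qnorm(x, p$mean, p$sd))
}

# mass of p^{1/3} below s, unnormalized, plus total; closed forms per family.
.compressed_mass <- function(dist, s) {
  p <- dist$params
  switch(dist$family,
    laplace = {
      # (e^{-|z|/tau}/(2 tau))^{1/3}: each flank integrates to 3 tau * (2 tau)^{-1/3}
      c0 <- (2 * p$tau)^(-1 / 3)
      half <- 3 * p$tau * c0
      z <- s - p$mu
      below <- ifelse(z < 0, half * exp(z / (3 * p$tau)),
                      half + half * (1 - exp(-z / (3 * p$tau))))
      list(below = below, total = 2 * half)
    },
    asymmetric_laplace = {
      hm <- 3 * p$tau_minus * p$A_minus^(1 / 3)
      hp <- 3 * p$tau_plus * p$A_plus^(1 / 3)
      below <- ifelse(s < 0, hm * exp(s / (3 * p$tau_minus)),
                      hm + hp * (1 - exp(-s / (3 * p$tau_plus))))
      list(below = below, total = hm + hp)
    },
    uniform = {
      w <- p$max - p$min
      list(below = pmin(pmax(s - p$min, 0), w) * w^(-1 / 3), total = w^(2 / 3))
    },
    truncated_power_law = {
      k <- .tpl_const(p)^(1 / 3); a <- p$exponent / 3
      s2 <- pmin(pmax(s, p$lower), p$upper)
      pr <- function(u) if (abs(a + 1) < 1e-12) log(u) else u^(a + 1) / (a + 1)
      list(below = k * (pr(s2) - pr(p$lower)),
           total = k * (pr(p$upper) - pr(p$lower)))
    },
    gaussian = {
      # dnorm^{1/3} is proportional to a normal density with sd * sqrt(3)
      tot <- (2 * pi)^(1 / 3) * sqrt(3) * p$sd^(2 / 3)
      list(below = tot * stats::pnorm(s, p$mean, p$sd * sqrt(3)), total = tot)
    })
}

#' Compressed (one-third power) cumulative distribution
#'
#' The cumulative distribution obtained by normalizing \eqn{p(s)^{1/3}}. Its
#' inverse, [qstim_compressed()], gives the large-population threshold
#' allocation that minimizes the mean squared error of the optimal linear
#' readout, the companding analogue of histogram equalization.
#'
#' @inheritParams dstim
#' @return probabilities in `[0, 1]`.
#' @export
pstim_compressed <- function(dist, s) {
  m <- .compressed_mass(dist, s)
  m$below / m$total
}

#' Compressed (one-third power) quantile function
#'
#' Returns the threshold \eqn{\theta} with
#' \eqn{Z \int_{-\infty}^{\theta} p^{1/3} = x}. For the symmetric Laplace this
#' is \eqn{3\log(2x)} for \eqn{x \le 1/2}, three times the plain quantile.
#'
#' @inheritParams qstim
#' @return stimulus values.
#' @export
qstim_compressed <- function(dist, x) {
  if (any(x <= 0 | x >= 1)) stop("quantile argument must lie strictly in (0, 1)")
  p <- dist$params
  switch(dist$family,
    laplace = p$mu + 3 * p$tau * ifelse(x < 0.5, log(2 * x), -log(2 * (1 - x))),
    asymmetric_laplace = {
      hm <- 3 * p$tau_minus * p$A_minus^(1 / 3)
      hp <- 3 * p$tau_plus * p$A_plus^(1 / 3)
      xm <- hm / (hm + hp)
      ifelse(x < xm, 3 * p$tau_minus * log(x / xm),
             -3 * p$tau_plus * log((1 - x) * (hm + hp) / hp))
    },
    uniform = stats::qunif(x, p$min, p$max),
    truncated_power_law = {
      k <- .tpl_const(p)^(1 / 3); a <- p$exponent / 3
      m <- .compressed_mass(dist, p$upper)$total
      if (abs(a + 1) < 1e-12) p$lower * exp(x * m / k)
      else ((x * m / k + p$lower^(a + 1) / (a + 1)) * (a + 1))^(1 / (a + 1))
    },
    gaussian = stats::qnorm(x, p$mean, p$sd * sqrt(3)))
}

#' Partial moments of the stimulus distribution
#'
#' Computes \eqn{\int_a^b s^k p(s) ds} for k = 0, 1, 2 over an interval, in
#' closed form for all built-in families. These are the building blocks of the
#' linear-readout solvers (interval masses, centers of mass, covariance terms).
#'
#' @inheritParams dstim
#' @param a,b interval endpoints (`-Inf`/`Inf` allowed).
#' @return a list with numeric elements `m0`, `m1`, `m2`.
#' @export
stim_partial_moments <- function(dist, a, b) {
  stopifnot(length(a) == length(b), all(b >= a))
  p <- dist$params
  switch(dist$family,
    laplace = .pm_alap(list(A_plus = 1 / (2 * p$tau), A_minus = 1 / (2 * p$tau),
                            tau_plus = p$tau, tau_minus = p$tau),
                       a - p$mu, b - p$mu, shift = p$mu),
    asymmetric_laplace = .pm_alap(p, a, b, shift = 0),
    uniform = {
      lo <- pmax(a, p$min); hi <- pmin(b, p$max)
      w <- pmax(hi - lo, 0); d <- 1 / (p$max - p$min)
      list(m0 = d * w,
           m1 = d * ifelse(w > 0, (hi^2 - lo^2) / 2, 0),
           m2 = d * ifelse(w > 0, (hi^3 - lo^3) / 3, 0))
    },
    truncated_power_law = {
      k <- .tpl_const(p)
      lo <- pmax(a, p$lower); hi <- pmin(b, p$upper)
      ok <- hi > lo
      pint <- function(e) {
        out <- numeric(length(lo))
        if (abs(e + 1) < 1e-12) out[ok] <- log(hi[ok] / lo[ok])
        else out[ok] <- (hi[ok]^(e + 1) - lo[ok]^(e + 1)) / (e + 1)
        out
      }
      e <- p$exponent
      list(m0 = k * pint(e), m1 = k * pint(e + 1), m2 = k * pint(e + 2))
    },
    gaussian = {
      mu <- p$mean; sg <- p$sd
      za <- (a - mu) / sg; zb <- (b - mu) / sg
      dP <- stats::pnorm(zb) - stats::pnorm(za)
      dphi <- stats::dnorm(zb) - stats::dnorm(za)
      # standard-normal pieces: int z phi = -dphi; int z^2 phi = dP - (z phi)|
      zphi <- function(z) ifelse(is.finite(z), z * stats::dnorm(z), 0)
      i1 <- -dphi
      i2 <- dP - (zphi(zb) - zphi(za))
      list(m0 = dP,
           m1 = mu * dP + sg * i1,
           m2 = mu^2 * dP + 2 * mu * sg * i1 + sg^2 * i2)
    })
}

# asymmetric-Laplace partial moments on the centered scale; `shift` re-centers
.pm_alap <- function(p, a, b, shift = 0) {
  Ap <- p$A_plus; Am <- p$A_minus; tp <- p$tau_plus; tm <- p$tau_minus
  # antiderivatives: positive flank F+(s) = int_0^s, negative F-(s) = int_s^0
  pos <- function(s, k) {
    # int_0^s u^k A+ e^{-u/tp} du, s >= 0 (s may be Inf)
    e <- exp(-s / tp)
    switch(k + 1L,
      Ap * tp * (1 - e),
      Ap * (tp^2 - ifelse(is.finite(s), e * tp * (s + tp), 0)),
      Ap * (2 * tp^3 - ifelse(is.finite(s), e * tp * (s^2 + 2 * s * tp + 2 * tp^2), 0)))
  }
  neg <- function(s, k) {
    # int_s^0 u^k A- e^{u/tm} du, s <= 0 (s may be -Inf)
    e <- exp(s / tm)
    switch(k + 1L,
      Am * tm * (1 - e),
      Am * (-tm^2 + ifelse(is.finite(s), e * tm * (tm - s), 0)),
      Am * (2 * tm^3 - ifelse(is.finite(s), e * tm * (s^2 - 2 * s * tm + 2 * tm^2), 0)))
  }
  piece <- function(k) {
    below <- ifelse(a < 0, neg(a, k), 0) - ifelse(b < 0, neg(pmin(b, 0), k), 0)
    above <- ifelse(b > 0, pos(b, k), 0) - ifelse(a > 0, pos(pmax(a, 0), k), 0)
    below + above
  }
  m0 <- piece(0L); m1 <- piece(1L); m2 <- piece(2L)
  if (shift != 0) {
    list(m0 = m0, m1 = m1 + shift * m0,
         m2 = m2 + 2 * shift * m1 + shift^2 * m0)
  } else list(m0 = m0, m1 = m1, m2 = m2)
}

#' Mean and variance of a stimulus distribution
#'
#' @inheritParams dstim
#' @return list with `mean`, `var`, `second_moment`.
#' @export
stim_moments <- function(dist) {
  m <- stim_partial_moments(dist, dist$support[1], dist$support[2])
  list(mean = m$m1, var = m$m2 - m$m1^2, second_moment = m$m2)
}
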