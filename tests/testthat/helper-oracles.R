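# Shared oracles: slow but independent reference computations.

# numeric cdf by adaptive quadrature of the density
quad_cdf <- function(dist, s) {
  lo <- dist$support[1]
  stats::integrate(function(u) dstim(dist, u), lo, s,
                   rel.tol = 1e-12, abs.tol = 1e-12)$value
}

# quantile by bisection on a cdf function
bisect_quantile <- function(cdf, x, lower, upper, tol = 1e-10) {
  stats::uniroot(function(s) cdf(s) - x, c(lower, upper), tol = tol)$root
}

# compressed cdf by quadrature of p^{1/3}
quad_compressed_cdf <- function(dist, s) {
  lo <- dist$support[1]
  tot <- stats::integrate(function(u) dstim(dist, u)^(1 / 3), lo,
                          dist$support[2], rel.tol = 1e-10)$value
  stats::integrate(function(u) dstim(dist, u)^(1 / 3), lo, s,
                   rel.tol = 1e-10)$value / tot
}

# homogeneous-ON cumulative positions -> response-region masses u_1 < ... < u_N
u_from_x <- function(x) rev(1 - x)

# brute-force MSE of a 2-level scalar quantizer of Unif(0,1) on a theta grid
lloyd2_grid_oracle <- function(n_grid = 2001) {
  thetas <- seq(0.01, 0.99, length.out = n_grid)
  mse <- vapply(thetas, function(th) {
    # optimal code values are interval means; MSE = sum of interval variances
    th^3 / 12 + (1 - th)^3 / 12
  }, 0)
  list(theta = thetas[which.min(mse)], mse = min(mse))
}

# random non-overlapping threshold profile in cumulative space
random_profile <- function(N, labels = NULL) {
  x <- sort(stats::runif(N, 0.02, 0.98))
  if (is.null(labels)) labels <- rep("N", N)
  threshold_profile(x, labels)
}
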