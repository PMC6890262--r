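laplace <- stimulus_distribution("laplace")

test_that("the noiseless solver reproduces the two-level quantizer of Unif(0,1)", {
  d <- stimulus_distribution("uniform")
  fit <- linear_readout(d, N = 1, m = 1)
  oracle <- lloyd2_grid_oracle()
  expect_equal(fit$theta, 0.5, tolerance = 1e-8)
  expect_equal(fit$theta, oracle$theta, tolerance = 1e-3)
  expect_equal(fit$w0, 0.25, tolerance = 1e-8)
  expect_equal(fit$weights, 0.5, tolerance = 1e-8)
  expect_equal(fit$mse, 1 / 48, tolerance = 1e-10)
  expect_equal(fit$mse, oracle$mse, tolerance = 1e-6)
})

test_that("the Lloyd alternation never increases the MSE", {
  for (N in c(4, 16, 64)) {
    fit <- linear_readout(laplace, N, N)
    expect_true(all(diff(fit$trace) <= 1e-10 * abs(fit$trace[-1]) + 1e-15))
  }
})

test_that("noiseless MSE scales as 1/N^2 and is mixture invariant", {
  Ns <- c(16, 32, 64, 128, 256)
  mses <- vapply(Ns, function(N) linear_readout(laplace, N, N)$mse, 0)
  slope <- unname(coef(stats::lm(log(mses) ~ log(Ns)))[2])
  expect_lt(abs(slope + 2), 0.1)
  # identical MSE for all mixtures of N = 64 cells
  ref <- linear_readout(laplace, 64, 64)
  for (m in c(0, 32)) {
    fit <- linear_readout(laplace, 64, m)
    expect_equal(fit$mse, ref$mse, tolerance = 1e-8)
    expect_equal(fit$theta, ref$theta, tolerance = 1e-8)
    # the analytic quadratic form agrees with the solver's own MSE
    expect_equal(evaluate_mse(fit), fit$mse, tolerance = 1e-10)
  }
})

test_that("large-N noiseless thresholds converge to the compressed quantile", {
  N <- 512
  fit <- linear_readout(laplace, N, N)
  pred <- qstim_compressed(laplace, seq_len(N) / (N + 1))
  central <- seq_len(N) >= 0.05 * N & seq_len(N) <= 0.95 * N
  expect_lt(max(abs(fit$theta[central] - pred[central])), 0.1)
})

test_that("the analytic MSE behaves correctly for degenerate and perturbed readouts", {
  mo <- stim_moments(laplace)
  # zero weights, w0 at the mean: MSE equals the stimulus variance
  ro <- list(theta = c(-1, 1), weights = c(0, 0), w0 = mo$mean,
             labels = c("F", "N"), dist = laplace, R = Inf)
  expect_equal(evaluate_mse(ro), mo$var, tolerance = 1e-12)
  # local optimality: perturbing one weight raises the MSE quadratically
  fit <- linear_readout(laplace, 4, 4)
  base <- evaluate_mse(fit)
  dmse <- vapply(c(1e-3, 2e-3, 4e-3), function(eps) {
    pert <- fit; pert$weights[2] <- pert$weights[2] + eps
    evaluate_mse(pert) - base
  }, 0)
  expect_true(all(dmse > 0))
  expect_equal(dmse[2] / dmse[1], 4, tolerance = 0.01)
  expect_equal(dmse[3] / dmse[2], 4, tolerance = 0.01)
})

test_that("stationarity: numeric gradients vanish at the converged solution", {
  for (cfg in list(list(N = 5, m = 5, R = Inf), list(N = 6, m = 4, R = 1))) {
    fit <- linear_readout(laplace, cfg$N, cfg$m, cfg$R)
    eps <- 1e-5
    grad_of <- function(get, set) {
      up <- set(fit, get(fit) + eps); dn <- set(fit, get(fit) - eps)
      (evaluate_mse(up) - evaluate_mse(dn)) / (2 * eps)
    }
    for (i in seq_len(cfg$N)) {
      gw <- grad_of(function(f) f$weights[i],
                    function(f, v) { f$weights[i] <- v; f })
      gt <- grad_of(function(f) f$theta[i],
                    function(f, v) { f$theta[i] <- v; f })
      expect_lt(abs(gw), 1e-5)
      expect_lt(abs(gt), 1e-5)
    }
    g0 <- grad_of(function(f) f$w0, function(f, v) { f$w0 <- v; f })
    expect_lt(abs(g0), 1e-5)
  }
})

test_that("the noisy solver recovers the noiseless fixed point as R grows", {
  f0 <- linear_readout(laplace, 8, 8, tol = 1e-13)
  fn <- linear_readout(laplace, 8, 8, R = 1e8, tol = 1e-13)
  expect_lt(max(abs(f0$theta - fn$theta)), 1e-4)
  expect_lt(max(abs(f0$weights - fn$weights)), 1e-4)
  expect_lt(abs(f0$mse - fn$mse) / f0$mse, 1e-6)
})

test_that("with noise the equal mixture beats the homogeneous population", {
  hom <- linear_readout(laplace, 40, 40, R = 1)
  mix <- linear_readout(laplace, 40, 20, R = 1)
  expect_lt(mix$mse, hom$mse * 0.8)
  # non-overlap of ON and OFF thresholds at the optimum
  expect_true(all(diff(mix$theta) > 0))
  # the homogeneous first threshold is far larger (more uncoded stimuli)
  expect_gt(hom$theta[1], mix$theta[1] + 1)
})

test_that("noisy homogeneous thresholds are linear in the bulk with a logarithmic tail", {
  N <- 100
  fit <- linear_readout(laplace, N, N, R = 1)
  idx <- seq_len(N)
  bulk <- idx >= 5 & idx <= 55        # below the median, dense linear region
  linfit <- stats::lm(fit$theta[bulk] ~ idx[bulk])
  expect_gt(summary(linfit)$r.squared, 0.999)
  # upper tail: theta grows like a log of the remaining index mass
  tail_idx <- idx >= 90 & idx <= 99
  logfit <- stats::lm(fit$theta[tail_idx] ~ log(1 - idx[tail_idx] / (N + 1)))
  expect_gt(summary(logfit)$r.squared, 0.995)
  expect_lt(coef(logfit)[2], 0)
})

test_that("asymptotic threshold laws track the numerical solver", {
  # homogeneous with noise: anchor and bulk within a small deviation
  N <- 100
  fit <- linear_readout(laplace, N, N, R = 1)
  af <- asymptotic_thresholds(laplace, N, N, R = 1)
  expect_lt(abs(attr(af, "theta1") - fit$theta[1]), 0.05)
  xs <- seq_len(N) / (N + 1)
  expect_lt(mean(abs(af(xs)[10:90] - fit$theta[10:90])), 0.15)
  # mixed: OFF branch is the closed-form exponential law
  fitm <- linear_readout(laplace, N, 80, R = 1)
  am <- asymptotic_thresholds(laplace, N, 80, R = 1)
  expect_lt(mean(abs(am(xs)[5:95] - fitm$theta[5:95])), 0.15)
  # unsupported family directs to the numerical solver
  expect_error(asymptotic_thresholds(stimulus_distribution("gaussian"),
                                     10, 10, R = 1), "Laplace")
})

test_that("the first-threshold equation matches its printed anchors", {
  expect_equal(first_threshold_mixed(1), 0, tolerance = 1e-6)
  expect_equal(round(first_threshold_mixed(1 / 4), 2), -0.79)
  # monotone in X, approaching 0 from below
  Xs <- c(0.05, 0.1, 0.25, 0.5, 0.9, 1)
  phis <- vapply(Xs, first_threshold_mixed, 0)
  expect_true(all(diff(phis) > 0 | phis[-1] == 0))
  expect_true(all(phis <= 0))
  expect_error(first_threshold_mixed(1.5), "in \\(0, 1\\]")
})

test_that("the OFF-fraction sweep finds the symmetric optimum and tracks stimulus bias", {
  sw <- sweep_off_fraction(laplace, 40, 1, alpha = c(0, 0.25, 0.4, 0.5, 0.6, 0.75, 1))
  expect_equal(sw$alpha_opt, 0.5)
  expect_equal(sw$curve$mse_normalized[1], 1)
  interior <- sw$curve$alpha > 0 & sw$curve$alpha < 1
  expect_true(all(sw$curve$mse_normalized[interior] < 1))
  # flat around the optimum, homogeneous clearly worst
  near <- sw$curve$mse[sw$curve$alpha %in% c(0.4, 0.5, 0.6)]
  expect_lt(max(near) / min(near), 1.05)
  # negative stimulus bias favors OFF cells, increasingly with the bias
  a2 <- sweep_off_fraction(
    stimulus_distribution("asymmetric_laplace", tau_plus = 1, tau_minus = 2),
    40, 1, alpha = seq(0.4, 0.9, by = 0.1))$alpha_opt
  a4 <- sweep_off_fraction(
    stimulus_distribution("asymmetric_laplace", tau_plus = 1, tau_minus = 4),
    40, 1, alpha = seq(0.4, 0.9, by = 0.1))$alpha_opt
  expect_gt(a2, 0.5)
  expect_gte(a4, a2)
  # noiseless: the curve is flat at 1 for every mixture
  sw0 <- sweep_off_fraction(laplace, 16, Inf, alpha = c(0, 0.25, 0.5, 1))
  expect_lt(max(abs(sw0$curve$mse_normalized - 1)), 1e-6)
})

test_that("predict/coef/residuals are consistent with the fitted decoder", {
  fit <- linear_readout(laplace, 6, 4, R = 2)
  s <- c(-3, -0.5, 0, 0.5, 3)
  y <- predict(fit, s = s)
  expect_equal(length(y), 5)
  expect_equal(residuals(fit, s = s), y - s)
  cf <- coef(fit)
  expect_equal(unname(cf["w0"]), fit$w0)
  # decoding the expected counts reproduces the deterministic decoder output
  act <- outer(s, fit$theta, ">=")
  off <- fit$labels == "F"
  act[, off] <- !act[, off, drop = FALSE]
  counts <- act * fit$R
  expect_equal(predict(fit, counts = counts), y)
})
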