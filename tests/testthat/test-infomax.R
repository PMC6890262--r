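test_that("noise entropy has the right limits and values", {
  expect_equal(noise_entropy(0), 0)
  # independent algebraic form at q = e^{-1}
  q <- exp(-1)
  direct <- -(log1p(-q) + q * log(q) / (1 - q))
  expect_equal(noise_entropy(q), direct, tolerance = 1e-14)
  expect_equal(noise_entropy(q), 1.04065, tolerance = 1e-5)
  # small-q expansion H_q ~ -q log q (next-order correction is +q)
  q <- exp(-10)
  expect_lt(abs(noise_entropy(q) - (-q * log(q))), 2 * q)
  expect_gt(noise_entropy(q), 0)
  expect_error(noise_entropy(1), "q must lie")
  expect_error(noise_entropy(-0.1), "q must lie")
})

test_that("closed-form maximal information matches printed optima", {
  expect_equal(round(max_information(2, R = 0.1)$bits, 3), 0.102)
  expect_equal(round(max_information(2, R = 1)$bits, 3), 0.771)
  expect_equal(signif(max_information(3, R = 1)$bits, 3), 1.04)
  expect_equal(signif(max_information(5, R = 1)$bits, 3), 1.47)
  expect_equal(signif(max_information(6, R = 10)$bits, 3), 2.81)
  # deterministic upper bound log(N + 1) at q = 0
  for (N in c(1, 4, 9))
    expect_equal(max_information(N, q = 0)$nats, log(N + 1))
})

test_that("maximal information is monotone in N and R and has the high-noise limit", {
  bits_N <- vapply(1:12, function(N) max_information(N, R = 0.5)$bits, 0)
  expect_true(all(diff(bits_N) > 0))
  Rs <- c(0.01, 0.1, 0.5, 1, 5, 20)
  bits_R <- vapply(Rs, function(R) max_information(4, R = R)$bits, 0)
  expect_true(all(diff(bits_R) > 0))
  # RN -> 0: I -> log(RN/e + 1)
  for (R in c(1e-4, 1e-5)) {
    N <- 10
    expect_equal(max_information(N, R = R)$nats, log(R * N / exp(1) + 1),
                 tolerance = 1e-3 * R * N)
  }
})

test_that("the optimal partition has equal interior intervals and correct limits", {
  part <- optimal_partition(6, 3, R = 1)
  expect_equal(sum(part$masses), 1, tolerance = 1e-12)
  expect_equal(part$p_edge, part$p / (1 - exp(-1)), tolerance = 1e-12)
  # large population regime: p_edge = p = p0 = 1/(N+1)
  part <- optimal_partition(1000, 500, R = 10)
  expect_equal(part$p_edge, 1 / 1001, tolerance = 1e-3)
  expect_equal(part$p0, 1 / 1001, tolerance = 1e-3)
  # high noise RN -> 0: p_edge -> 1/e, p0 -> 1 - 2/e
  part <- optimal_partition(10, 5, R = 1e-6)
  expect_equal(part$p_edge, exp(-1), tolerance = 1e-4)
  expect_equal(part$p0, 1 - 2 * exp(-1), tolerance = 1e-4)
  # q = 0 makes the edge interval equal the interior ones
  part <- optimal_partition(5, 5, q = 0)
  expect_equal(part$p_edge, part$p)
})

test_that("Equal Coding Theorem: every non-overlapping mixture attains the closed form", {
  for (R in c(0.1, 1, 10)) {
    ref <- max_information(4, R = R)$nats
    for (m in 0:4) {
      prof <- optimal_thresholds(4, m, R = R)
      expect_equal(exact_information(prof, R = R)$nats, ref,
                   tolerance = 1e-10)
    }
  }
  # single ON cell, q -> 0: median split
  prof <- optimal_thresholds(1, 1, q = 0)
  expect_equal(prof$x, 0.5)
  expect_error(optimal_thresholds(3, R = 1, labels = "NFN"), "overlap")
})

test_that("optimal threshold gaps equal the closed-form interval mass", {
  prof <- optimal_thresholds(4, 4, R = 1)
  part <- optimal_partition(4, 4, R = 1)
  expect_equal(diff(prof$x), rep(part$p, 3), tolerance = 1e-12)
  expect_equal(1 - prof$x[4], part$p_edge, tolerance = 1e-12)
  # grid-search oracle: no equal-mass perturbation improves the information
  base <- exact_information(prof, R = 1)$nats
  grid <- as.matrix(expand.grid(d1 = c(-0.02, 0, 0.02), d2 = c(-0.02, 0, 0.02),
                                d3 = c(-0.02, 0, 0.02), d4 = c(-0.02, 0, 0.02)))
  vals <- apply(grid, 1, function(dd) {
    x <- sort(pmin(pmax(prof$x + dd, 1e-6), 1 - 1e-6))
    exact_information(x, R = 1, labels = prof$labels)$nats
  })
  expect_lt(max(vals), base + 1e-12)
})

test_that("pattern enumeration and the recursion agree on homogeneous populations", {
  # trivial single-cell channel
  expect_equal(information_recursive(0.5, q = 0)$bits, 1)
  expect_equal(exact_information(0.5, q = 0, labels = "N")$bits, 1)
  # printed two-cell optimum
  prof <- optimal_thresholds(2, 2, R = 1)
  expect_equal(round(information_recursive(u_from_x(prof$x), R = 1)$bits, 3),
               0.771)
  # property: random profiles, random noise levels
  set.seed(42)
  for (rep in 1:40) {
    N <- sample(1:6, 1)
    x <- sort(stats::runif(N, 0.05, 0.95))
    q <- stats::runif(1, 0, 0.95)
    a <- exact_information(x, q = q, labels = strrep("N", N))$nats
    b <- information_recursive(u_from_x(x), q = q)$nats
    expect_equal(a, b, tolerance = 1e-10)
  }
  expect_error(information_recursive(c(0.5, 0.2), q = 0.1), "sorted")
  expect_error(exact_information(rep(0.5, 21), q = 0.1,
                                 labels = strrep("N", 21)), "enumeration")
})

test_that("interval readjustment after observing silent cells reproduces the sub-population optimum", {
  # conditional-information decomposition: revising the optimal N-cell
  # profile by the first silent ON cell gives the optimal (N-1)-cell profile
  N <- 5; R <- 1; q <- exp(-R)
  u <- u_from_x(optimal_thresholds(N, N, R = R)$x)
  u_rev <- (u[-1] - u[1] * (1 - q)) / (1 - u[1] * (1 - q))
  u_sub <- u_from_x(optimal_thresholds(N - 1, N - 1, R = R)$x)
  expect_equal(u_rev, u_sub, tolerance = 1e-12)
})

test_that("numerical optimization reproduces the printed configuration table", {
  # fixed labels, no overlap: matches the closed form
  r <- optimize_thresholds(2, R = 1, mode = "fixed_labels", labels = "NN",
                           restarts = 4, seed = 1)
  expect_equal(round(r$information$bits, 3), 0.771)
  # enforced overlap, two cells at R = 0.1: best configuration NF
  r <- optimize_thresholds(2, R = 0.1, mode = "fixed_labels", labels = "NF",
                           restarts = 6, seed = 1)
  expect_equal(signif(r$information$bits, 3), 0.0952)
  # three cells at R = 1: free optimization attains the closed form with
  # non-overlapping labels; enforced overlap reaches 1.00 bits via FNF/NFN
  free <- optimize_thresholds(3, R = 1, mode = "allow_overlap",
                              restarts = 4, seed = 2)
  expect_equal(signif(free$information$bits, 3), 1.04)
  expect_false(grepl("NF", free$labels)) # no ON threshold below an OFF one
  top <- free$per_label
  winners <- top$labels[top$bits >= max(top$bits) - 1e-3]
  expect_setequal(winners, c("FFF", "FFN", "FNN", "NNN"))
  forced <- optimize_thresholds(3, R = 1, mode = "enforce_overlap",
                                restarts = 4, seed = 3)
  expect_equal(signif(forced$information$bits, 3), 1.00)
  expect_true(forced$labels %in% c("FNF", "NFN"))
})

test_that("mean spike count reproduces the large-population and high-noise laws", {
  R <- 1; N <- 200
  # homogeneous: r(0) = R/2
  prof <- optimal_thresholds(N, N, R = R)
  expect_equal(mean_spike_count(prof, R), R / 2, tolerance = 0.01)
  # equal mixture: half the homogeneous cost
  prof <- optimal_thresholds(N, N / 2, R = R)
  expect_equal(mean_spike_count(prof, R), R / 4, tolerance = 0.01)
  # high noise RN -> 0: R/e for any mixture
  R <- 1e-5; N <- 10
  for (m in c(0, 5, 10)) {
    prof <- optimal_thresholds(N, m, R = R)
    expect_equal(mean_spike_count(prof, R), R / exp(1), tolerance = 1e-3)
  }
})
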