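# Forward Poisson spiking simulator and Monte-Carlo estimators.

# run code with a locally-set RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# activation of each neuron at each stimulus: ON fires for s >= theta,
# OFF for s < theta (half-open convention, so exactly one regime at s = theta)
.activations_at <- function(profile, s) {
  on <- profile$labels == "N"
  th <- profile$theta
  if (is.null(th)) stop("profile carries no stimulus-space thresholds; ",
                        "attach a distribution")
  act <- outer(s, th, ">=")
  act[, !on] <- !act[, !on, drop = FALSE]
  act
}

#' Simulate Poisson spike counts from a binary-rate population
#'
#' Each neuron fires Poisson spikes with expected count `R` per coding window
#' whenever the stimulus is inside its response region (ON: `s >= theta`;
#' OFF: `s < theta`), and is exactly silent otherwise. Raw counts are kept so
#' the `1/R`-normalized linear decoder can be simulated faithfully; lumping
#' to binary states happens at analysis time.
#'
#' @param profile a [threshold_profile()] with stimulus-space thresholds.
#' @param R expected spike count per active neuron.
#' @param stimuli numeric vector of stimulus values (one per trial).
#' @param seed integer seed; reproducibility is part of the contract.
#' @return object of class `spike_batch`: `stimuli`, `counts` (trials x
#'   neurons), `R`, `labels`, `theta`.
#' @export
simulate_responses <- function(profile, R, stimuli, seed = NULL) {
  stopifnot(inherits(profile, "threshold_profile"), R >= 0)
  act <- .activations_at(profile, stimuli)
  counts <- .with_seed(seed, {
    k <- stats::rpois(length(act), R * as.numeric(act))
    matrix(k, nrow = length(stimuli))
  })
  structure(list(stimuli = stimuli, counts = counts, R = R,
                 labels = profile$labels, theta = profile$theta),
            class = "spike_batch")
}

#' @export
print.spike_batch <- function(x, ...) {
  cat(sprintf("Spike batch: %d trials x %d neurons, R = %g\n",
              nrow(x$counts), ncol(x$counts), x$R))
  cat(sprintf("  mean count per neuron: %.4g\n", mean(x$counts)))
  invisible(x)
}

#' Monte-Carlo estimate of the mutual information
#'
#' Plug-in estimate of the stimulus-response mutual information of a
#' threshold profile from simulated binarized responses, with a jackknife
#' standard error. Stimuli enter only through the interval between sorted
#' thresholds they fall in, so sampling is done in cumulative space and the
#' estimator is distribution-free, consistent for [exact_information()].
#'
#' @inheritParams exact_information
#' @param n_trials number of simulated trials (>= 1e4 recommended).
#' @param seed integer seed.
#' @return list with `bits`, `nats`, `se_bits`, `n_trials`.
#' @export
mc_mutual_information <- function(profile, R = NULL, q = NULL,
                                  n_trials = 1e4, seed = NULL) {
  q <- .resolve_q(R, q)
  if (inherits(profile, "threshold_profile")) x <- profile$x
  else x <- profile
  N <- length(x)
  labels <- if (inherits(profile, "threshold_profile")) profile$labels
            else rep("N", N)
  A <- .activation(labels)
  .with_seed(seed, {
    u <- stats::runif(n_trials)
    k <- findInterval(u, x) + 1L            # interval row index, 1..N+1
    act <- A[k, , drop = FALSE]
    fired <- act & (matrix(stats::runif(n_trials * N), n_trials) > q)
    code <- as.integer(fired %*% 2^(seq_len(N) - 1))
    tab <- table(interval = k, pattern = code)
    counts <- as.matrix(tab)
    est <- .plugin_mi(counts)
    # jackknife over trials, grouped by (interval, pattern) cell
    cells <- which(counts > 0, arr.ind = TRUE)
    mi_loo <- numeric(nrow(cells))
    for (ci in seq_len(nrow(cells))) {
      cc <- counts
      cc[cells[ci, 1], cells[ci, 2]] <- cc[cells[ci, 1], cells[ci, 2]] - 1L
      mi_loo[ci] <- .plugin_mi(cc)
    }
    wts <- counts[cells]
    mbar <- sum(wts * mi_loo) / n_trials
    se <- sqrt((n_trials - 1) / n_trials * sum(wts * (mi_loo - mbar)^2))
    list(bits = est / log(2), nats = est, se_bits = se / log(2),
         n_trials = n_trials)
  })
}

.plugin_mi <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  pr <- rowSums(p); pc <- colSums(p)
  i <- p > 0
  sum(p[i] * (log(p[i]) - log(outer(pr, pc))[i]))
}

#' Monte-Carlo estimate of the readout mean squared error
#'
#' Simulates Poisson spike counts, decodes with the `1/R`-normalized linear
#' readout, and estimates the MSE with its standard error. Consistent for the
#' analytic [evaluate_mse()].
#'
#' @inheritParams evaluate_mse
#' @param n_trials number of simulated trials.
#' @param seed integer seed.
#' @return list with `mse`, `se`, `n_trials`.
#' @export
mc_mse <- function(readout, dist = NULL, R = NULL, n_trials = 1e4,
                   seed = NULL) {
  dist <- dist %||% readout$dist
  R <- R %||% readout$R
  .with_seed(seed, {
    s <- qstim(dist, stats::runif(n_trials))
    prof <- threshold_profile(pstim(dist, readout$theta), readout$labels, dist)
    act <- .activations_at(prof, s)
    if (is.infinite(R)) {
      y <- drop(act %*% readout$weights) + readout$w0
    } else {
      counts <- matrix(stats::rpois(length(act), R * as.numeric(act)),
                       nrow = n_trials)
      y <- drop(counts %*% readout$weights) / R + readout$w0
    }
    err2 <- (y - s)^2
    list(mse = mean(err2), se = stats::sd(err2) / sqrt(n_trials),
         n_trials = n_trials)
  })
}

#' Generate synthetic power-law distributed thresholds
#'
#' Draws i.i.d. activation thresholds from a truncated power-law density
#' \eqn{p(\theta) \propto \theta^{exponent}} on `(lower, cutoff)` by inverse
#' cdf sampling — a synthetic stand-in for pooled dose-response activation
#' thresholds (EC50 values) such as those measured across olfactory receptor
#' neurons.
#'
#' @param exponent density exponent (e.g. -0.58).
#' @param cutoff upper cutoff of the threshold distribution.
#' @param n number of thresholds.
#' @param lower lower cutoff (default 1).
#' @param seed integer seed.
#' @return numeric vector of thresholds.
#' @export
generate_power_law_thresholds <- function(exponent, cutoff, n, lower = 1,
                                          seed = NULL) {
  d <- stimulus_distribution("truncated_power_law", exponent = exponent,
                             lower = lower, upper = cutoff)
  .with_seed(seed, qstim(d, stats::runif(n)))
}
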