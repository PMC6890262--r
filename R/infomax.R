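#' Noise entropy of a binary Poisson neuron
#'
#' For a binary-rate Poisson neuron with expected spike count `R` in the
#' coding window, the probability that an active neuron stays silent is
#' \eqn{q = e^{-R}}. The noise entropy is
#' \deqn{H_q = -[(1-q)\log(1-q) + q \log q] / (1-q),}
#' in nats, with \eqn{H_0 = 0} by continuity. It is the entropy of the
#' geometric count distribution \eqn{p(k) = (1-q) q^k} and plays the role of
#' the response entropy conditional on the stimulus in the large-population
#' regime.
#'
#' @param q noise parameter in `[0, 1)`; `q = 0` is the exact noiseless limit.
#' @return entropy in nats.
#' @export
noise_entropy <- function(q) {
  if (any(q < 0 | q >= 1)) stop("noise parameter q must lie in [0, 1)")
  out <- numeric(length(q))
  pos <- q > 0
  qq <- q[pos]
  out[pos] <- -((1 - qq) * log1p(-qq) + qq * log(qq)) / (1 - qq)
  out
}

# convert R (expected spike count) to q, allowing R = Inf
.q_from_R <- function(R) {
  if (any(R < 0)) stop("expected spike count R must be nonnegative")
  exp(-R)
}

#' Maximal mutual information of an optimized ON/OFF population
#'
#' Closed-form maximum of the stimulus-response mutual information for a
#' population of `N` binary ON/OFF Poisson neurons with optimized thresholds:
#' \deqn{I = \log(1 + N e^{-H_q}),}
#' independent of the ON/OFF mixture and of the stimulus distribution
#' (Equal Coding Theorem). At `q = 0` it reaches the deterministic bound
#' `log(N + 1)`; in the high-noise regime it approaches `log(RN/e + 1)`.
#'
#' @param N number of neurons (>= 1).
#' @param R expected spike count per active neuron; alternatively supply `q`.
#' @param q noise parameter `e^{-R}`; exactly one of `R`, `q` is needed.
#' @return list of class `coding_information` with `nats` and `bits`.
#' @examples
#' max_information(2, R = 1) # 0.771 bits
#' @export
max_information <- function(N, R = NULL, q = NULL) {
  q <- .resolve_q(R, q)
  if (any(N < 1)) stop("N must be >= 1")
  nats <- log1p(N * exp(-noise_entropy(q)))
  structure(list(nats = nats, bits = nats / log(2)),
            class = "coding_information")
}

#' @export
print.coding_information <- function(x, ...) {
  cat(sprintf("Mutual information: %.6g bits (%.6g nats)\n", x$bits, x$nats))
  if (!is.null(x$diagnostics))
    cat(sprintf("  (%s)\n", x$diagnostics))
  invisible(x)
}

.resolve_q <- function(R, q) {
  if (is.null(q) && is.null(R)) stop("supply either R or q")
  if (!is.null(q) && !is.null(R) && any(abs(q - exp(-R)) > 1e-12))
    stop("inconsistent R and q supplied")
  if (is.null(q)) q <- .q_from_R(R)
  if (any(q < 0 | q >= 1)) stop("q must lie in [0, 1)")
  q
}

#' Optimal interval partition of stimulus probability
#'
#' The information-maximizing thresholds cut stimulus space into intervals of
#' probability mass `p = 1/(N + exp(H_q))` between consecutive same-type
#' thresholds, `p_edge = p/(1-q)` beyond the outermost ON and OFF thresholds,
#' and a silent interval between the two polarities absorbing the remainder.
#' For a homogeneous population there is a single edge interval and the
#' silent interval sits at the inactive end.
#'
#' @param N population size.
#' @param m number of ON cells (`0 <= m <= N`).
#' @inheritParams max_information
#' @return list with `p`, `p_edge`, `p0` and the full vector `masses` of the
#'   `N + 1` interval masses ordered from low to high stimulus values.
#' @export
optimal_partition <- function(N, m = N, R = NULL, q = NULL) {
  q <- .resolve_q(R, q)
  stopifnot(N >= 1, m >= 0, m <= N)
  Hq <- noise_entropy(q)
  p <- 1 / (N + exp(Hq))
  p_edge <- p / (1 - q)
  homog <- (m == 0 || m == N)
  p0 <- if (homog) 1 - (N - 1) * p - p_edge else 1 - (N - 2) * p - 2 * p_edge
  stopifnot(p0 >= -1e-12)
  p0 <- max(p0, 0)
  n_off <- N - m
  masses <- if (m == N) {         # all ON: silent interval at the bottom
    c(p0, rep(p, N - 1), p_edge)
  } else if (m == 0) {            # all OFF: silent interval at the top
    c(p_edge, rep(p, N - 1), p0)
  } else {
    c(p_edge, rep(p, n_off - 1), p0, rep(p, m - 1), p_edge)
  }
  list(p = p, p_edge = p_edge, p0 = p0, masses = masses)
}

#' Construct a threshold profile
#'
#' A `threshold_profile` couples sorted thresholds, their cumulative positions
#' under a stimulus distribution, and the ON/OFF identity of each threshold.
#' Labels use the convention `"F"` = OFF, `"N"` = ON, ordered along the sorted
#' thresholds (e.g. `"FFN"`).
#'
#' @param x cumulative threshold positions in (0, 1), nondecreasing.
#' @param labels character label string over \{F, N\} or character vector.
#' @param dist optional [stimulus_distribution()]; when given, stimulus-space
#'   thresholds are attached via the quantile map.
#' @return object of class `threshold_profile`.
#' @export
threshold_profile <- function(x, labels, dist = NULL) {
  labels <- .parse_labels(labels, length(x))
  if (is.unsorted(x)) stop("cumulative positions must be sorted")
  if (any(x <= 0 | x >= 1)) stop("cumulative positions must lie in (0, 1)")
  theta <- if (!is.null(dist)) qstim(dist, x) else NULL
  structure(list(x = x, theta = theta, labels = labels, dist = dist),
            class = "threshold_profile")
}

.parse_labels <- function(labels, N) {
  if (length(labels) == 1 && is.character(labels))
    labels <- strsplit(labels, "")[[1]]
  labels <- toupper(as.character(labels))
  if (length(labels) != N) stop("label string length must equal N")
  if (!all(labels %in% c("F", "N"))) stop("labels must be 'F' (OFF) or 'N' (ON)")
  labels
}

.is_nonoverlapping <- function(labels) {
  # all OFF thresholds below all ON thresholds
  !is.unsorted(match(labels, c("F", "N")))
}

#' @export
print.threshold_profile <- function(x, ...) {
  N <- length(x$x)
  cat(sprintf("Threshold profile: N = %d  [%s]\n", N,
              paste(x$labels, collapse = "")))
  cat("  cumulative positions:", paste(signif(x$x, 4), collapse = " "), "\n")
  if (!is.null(x$theta))
    cat("  thresholds:", paste(signif(x$theta, 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.threshold_profile <- function(x, ...) {
  N <- length(x$x)
  graphics::plot(x$x, seq_len(N), type = "s", xlim = c(0, 1),
                 xlab = "cumulative stimulus position",
                 ylab = "threshold index",
                 col = ifelse(x$labels == "N", "red", "blue"), ...)
  invisible(x)
}

#' Information-maximizing thresholds for a non-overlapping population
#'
#' Places the `N` thresholds of a non-overlapping ON/OFF mixture (all OFF
#' thresholds below all ON thresholds) at the closed-form optimum: interval
#' masses follow [optimal_partition()], and stimulus-space thresholds are
#' obtained through the quantile map of `dist`. Any mixture placed this way
#' attains [max_information()] exactly (Equal Coding Theorem).
#'
#' @inheritParams optimal_partition
#' @param labels optional label string; must be non-overlapping. Defaults to
#'   `m` ON cells above `N - m` OFF cells.
#' @param dist stimulus distribution (defaults to the symmetric Laplace).
#' @return a [threshold_profile()].
#' @export
optimal_thresholds <- function(N, m = N, R = NULL, q = NULL, labels = NULL,
                               dist = stimulus_distribution("laplace")) {
  q <- .resolve_q(R, q)
  if (!is.null(labels)) {
    labels <- .parse_labels(labels, N)
    if (!.is_nonoverlapping(labels))
      stop("labels overlap (an ON threshold lies below an OFF threshold); ",
           "use optimize_thresholds() for overlapping configurations")
    m <- sum(labels == "N")
  } else {
    labels <- c(rep("F", N - m), rep("N", m))
  }
  part <- optimal_partition(N, m, q = q)
  x <- cumsum(part$masses)[seq_len(N)]
  threshold_profile(x, labels, dist)
}

# cache of binary pattern matrices
.pattern_env <- new.env(parent = emptyenv())
.patterns <- function(N) {
  key <- as.character(N)
  if (is.null(.pattern_env[[key]])) {
    B <- as.matrix(expand.grid(rep(list(0:1), N)))
    dimnames(B) <- NULL
    .pattern_env[[key]] <- B
  }
  .pattern_env[[key]]
}

# binary entropy in nats with 0 log 0 = 0
.h2 <- function(u) {
  out <- numeric(length(u))
  i <- u > 0 & u < 1
  out[i] <- -u[i] * log(u[i]) - (1 - u[i]) * log1p(-u[i])
  out
}

# activation matrix: rows = N+1 stimulus intervals, cols = neurons.
# interval k (1-based row k means k-1 thresholds below s): ON neuron j active
# iff k-1 >= j; OFF neuron j active iff k-1 < j.
.activation <- function(labels) {
  N <- length(labels)
  k <- matrix(0:N, N + 1, N)
  j <- matrix(seq_len(N), N + 1, N, byrow = TRUE)
  on <- matrix(labels == "N", N + 1, N, byrow = TRUE)
  (on & k >= j) | (!on & k < j)
}

#' Exact mutual information of a threshold profile
#'
#' Computes the stimulus-response mutual information of an arbitrary (possibly
#' overlapping) ON/OFF threshold configuration by enumerating all `2^N` binary
#' response patterns against the `N + 1` stimulus intervals. Spike counts are
#' lumped to binary states \{0, >=1\}: an active neuron is silent with
#' probability `q` and fires with probability `1 - q`, which is information-
#' equivalent to the full Poisson count distribution.
#'
#' @param profile a [threshold_profile()], or a numeric vector of cumulative
#'   positions together with `labels`.
#' @param labels label string, only needed when `profile` is a bare vector.
#' @inheritParams max_information
#' @return `coding_information` (nats and bits).
#' @export
exact_information <- function(profile, R = NULL, q = NULL, labels = NULL) {
  q <- .resolve_q(R, q)
  if (inherits(profile, "threshold_profile")) {
    x <- profile$x; labels <- profile$labels
  } else {
    x <- profile; labels <- .parse_labels(labels, length(x))
  }
  N <- length(x)
  if (N > 20) stop("pattern enumeration infeasible for N > 20; ",
                   "use mc_mutual_information() instead")
  masses <- diff(c(0, x, 1))
  A <- .activation(labels)
  B <- .patterns(N)
  ones <- rowSums(B)
  marg <- numeric(nrow(B))
  h_cond <- 0
  for (k in seq_len(N + 1)) {
    if (masses[k] <= 0) next
    a <- A[k, ]
    na <- sum(a)
    valid <- B %*% (1 - a) == 0
    pk <- numeric(nrow(B))
    pk[valid] <- (1 - q)^ones[valid] * q^(na - ones[valid])
    marg <- marg + masses[k] * pk
    h_cond <- h_cond + masses[k] * na * .h2(1 - q)
  }
  pos <- marg > 0
  h_resp <- -sum(marg[pos] * log(marg[pos]))
  nats <- max(h_resp - h_cond, 0)
  structure(list(nats = nats, bits = nats / log(2)),
            class = "coding_information")
}

#' Recursive mutual information for a homogeneous ON population
#'
#' Evaluates the nested chain-rule form of the information for `N` ON cells
#' with response-region masses `0 < u_1 < ... < u_N < 1` (`u_i` is the
#' stimulus mass above the `i`-th largest threshold):
#' \deqn{I_N = g(u_1) + (1 - u_1(1-q))[g(u_2^{(1)}) + \dots]}
#' with \eqn{g(u) = h(u(1-q)) - u h(1-q)} and each observation of a silent
#' cell revising the remaining masses to
#' \eqn{u_i' = (u_i - u_1(1-q)) / (1 - u_1(1-q))}.
#'
#' @param u increasing vector of response-region masses in (0, 1).
#' @inheritParams max_information
#' @return `coding_information`.
#' @export
information_recursive <- function(u, R = NULL, q = NULL) {
  q <- .resolve_q(R, q)
  if (is.unsorted(u, strictly = FALSE)) stop("u must be sorted increasing")
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly in (0, 1)")
  g <- function(v) .h2(v * (1 - q)) - v * .h2(1 - q)
  nats <- 0
  weight <- 1
  while (length(u) > 0) {
    u1 <- u[1]
    nats <- nats + weight * g(u1)
    shrink <- 1 - u1 * (1 - q)
    weight <- weight * shrink
    u <- (u[-1] - u1 * (1 - q)) / shrink
  }
  structure(list(nats = nats, bits = nats / log(2)),
            class = "coding_information")
}

#' Numerically optimize thresholds for a given ON/OFF configuration
#'
#' Maximizes [exact_information()] over the cumulative thresholds for one or
#' many label strings. Interval masses are parameterized on the
#' `(N+1)`-simplex through a softmax map and optimized with a quasi-Newton
#' method from multiple random restarts (with a Nelder-Mead fallback), which
#' handles the multimodality across configurations by explicit enumeration of
#' label strings rather than by the continuous optimizer.
#'
#' @param N population size (<= 10 for label enumeration modes).
#' @inheritParams max_information
#' @param mode `"fixed_labels"` optimizes the supplied `labels`;
#'   `"allow_overlap"` enumerates all `2^N` label strings and returns the
#'   best; `"enforce_overlap"` restricts the enumeration to configurations in
#'   which at least one ON threshold lies below an OFF threshold.
#' @param labels label string for `mode = "fixed_labels"`.
#' @param restarts random restarts per label string.
#' @param tol convergence tolerance on the information (nats).
#' @param seed optional seed controlling the restart draws.
#' @return object of class `infomax_opt`: best `profile` (cumulative
#'   positions), `information` (`coding_information`), `labels`, `converged`,
#'   and `per_label` table of the optimum for every configuration tried.
#' @export
optimize_thresholds <- function(N, R = NULL, q = NULL,
                                mode = c("fixed_labels", "allow_overlap",
                                         "enforce_overlap"),
                                labels = NULL, restarts = 10, tol = 1e-10,
                                seed = NULL) {
  mode <- match.arg(mode)
  q <- .resolve_q(R, q)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  label_sets <- switch(mode,
    fixed_labels = {
      if (is.null(labels)) stop("labels required for mode = 'fixed_labels'")
      list(.parse_labels(labels, N))
    },
    allow_overlap = ,
    enforce_overlap = {
      if (N > 10) stop("label enumeration limited to N <= 10; use fixed_labels")
      all_lab <- .all_label_strings(N)
      if (mode == "enforce_overlap")
        all_lab <- Filter(function(l) !.is_nonoverlapping(l), all_lab)
      all_lab
    })
  per <- lapply(label_sets, function(lab)
    .optimize_one_labeling(N, q, lab, restarts, tol))
  bits <- vapply(per, function(r) r$nats / log(2), 0)
  best <- which.max(bits)
  per_label <- data.frame(
    labels = vapply(label_sets, paste, "", collapse = ""),
    bits = bits,
    converged = vapply(per, `[[`, TRUE, "converged"))
  res <- per[[best]]
  info <- structure(list(nats = res$nats, bits = res$nats / log(2)),
                    class = "coding_information")
  structure(list(
    profile = threshold_profile(res$x, label_sets[[best]]),
    information = info,
    labels = paste(label_sets[[best]], collapse = ""),
    mode = mode, N = N, q = q,
    converged = res$converged,
    per_label = per_label[order(-per_label$bits), , drop = FALSE]),
    class = "infomax_opt")
}

.all_label_strings <- function(N) {
  grid <- expand.grid(rep(list(c("F", "N")), N), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ], use.names = FALSE))
}

.optimize_one_labeling <- function(N, q, labels, restarts, tol) {
  obj <- function(z) {
    w <- exp(c(0, z) - max(c(0, z)))
    x <- cumsum(w / sum(w))[seq_len(N)]
    x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
    -exact_information(x, q = q, labels = labels)$nats
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    z0 <- if (r == 1) rep(0, N) else stats::rnorm(N, 0, 1.5)
    fit <- tryCatch(
      stats::optim(z0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = tol)),
      error = function(e) NULL)
    if (is.null(fit))
      fit <- stats::optim(z0, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = tol))
    # polish with Nelder-Mead to escape flat softmax directions
    fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = tol))
    if (fit2$value < fit$value) fit <- fit2
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  w <- exp(c(0, best$par) - max(c(0, best$par)))
  x <- cumsum(w / sum(w))[seq_len(N)]
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  list(x = x, nats = -best$value,
       converged = isTRUE(best$convergence == 0))
}

#' @export
print.infomax_opt <- function(x, ...) {
  cat(sprintf("Threshold optimization (mode = %s), N = %d, q = %.4g\n",
              x$mode, x$N, x$q))
  cat(sprintf("  best configuration: %s  I = %.4g bits%s\n", x$labels,
              x$information$bits,
              if (x$converged) "" else "  [not converged]"))
  if (nrow(x$per_label) > 1) {
    cat("  top configurations:\n")
    top <- utils::head(x$per_label, 8)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %s  %.4g bits\n", top$labels[i], top$bits[i]))
  }
  invisible(x)
}

#' Mean spike count per neuron of an ON/OFF population
#'
#' The expected number of spikes per neuron per coding window,
#' \eqn{r = (R/N) \sum_i P(\mathrm{neuron}\ i\ \mathrm{active})}, where the
#' activation probability is the stimulus mass of the neuron's response
#' region. For the infomax-optimal thresholds this reproduces
#' \eqn{r(\alpha) = R(\alpha^2 + (1-\alpha)^2)/2} in the large-population
#' regime (with \eqn{\alpha} the OFF fraction) and \eqn{r = R/e} in the
#' high-noise regime.
#'
#' @param profile a [threshold_profile()].
#' @param R expected spike count per active neuron.
#' @return mean spikes per neuron per coding window.
#' @export
mean_spike_count <- function(profile, R) {
  stopifnot(inherits(profile, "threshold_profile"), R >= 0)
  on <- profile$labels == "N"
  p_active <- ifelse(on, 1 - profile$x, profile$x)
  R * mean(p_active)
}
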