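---
title: "Methods: efficient coding by ON/OFF Poisson populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: efficient coding by ON/OFF Poisson populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onoffcoding)
```

## The model and its assumptions

A scalar stimulus $s \sim p(s)$ is encoded by $N$ neurons with *binary*
rate functions: an ON cell with threshold $\theta_i$ fires Poisson spikes
with expected count $R = \nu_{max} T$ in a coding window $T$ whenever
$s \ge \theta_i$ and is exactly silent otherwise; an OFF cell is the mirror
image ($s < \theta_i$). Conditional on the stimulus, neurons are
independent. The binary-rate assumption is what makes the problem exactly
solvable: for mutual information the Poisson counts can be lumped into
binary states $\{0, \ge 1\}$ without information loss, so an active neuron
is "silent by accident" with probability $q = e^{-R}$. The package treats
$q$ (or $R$) as the single noise parameter: $q \to 0$ is deterministic
coding, $q \to 1$ the high-noise regime. $q = 0$ is implemented as an exact
branch so the noiseless limit never touches $\log 0$.

What the model leaves out: graded (multi-level) rate functions, spontaneous
firing, sub-Poisson count statistics, input noise upstream of the
nonlinearity, and temporal structure inside the coding window. Only
conditionally independent noise is simulated.

## Information quantities

`exact_information()` enumerates all $2^N$ binarized response patterns
against the $\le N+1$ stimulus intervals cut by the sorted thresholds.
Because the stimulus enters only through the interval masses, the
computation is distribution-free; it is exact for arbitrary, including
overlapping, ON/OFF configurations and refuses $N > 20$ (the Monte-Carlo
estimator covers larger populations). `information_recursive()` evaluates
the equivalent chain-rule form for homogeneous populations,
$I_N = g(u_1) + (1 - u_1(1-q)) [\, g(u_2^{(1)}) + \cdots ]$ with
$g(u) = h(u(1-q)) - u\,h(1-q)$, where each factor conditions on one more
cell having stayed silent and rescales the remaining response-region
masses. The two routes agree to $10^{-10}$ nats on random inputs, which is
the package's main internal consistency check; the Monte-Carlo plug-in
estimator (with jackknife standard errors) provides a third, stochastic
route.

The closed-form optimum $I = \log(1 + N e^{-H_q})$ with noise entropy
$H_q = -[(1-q)\log(1-q) + q\log q]/(1-q)$ holds for every non-overlapping
ON/OFF mixture (Equal Coding Theorem), and the optimal interval masses are
$p = 1/(N + e^{H_q})$ inside, $p_{edge} = p/(1-q)$ at the two outer edges,
and a silent interval absorbing the remainder between the polarities.
Profiles are constructed directly from these interval masses rather than
from per-index threshold formulas (whose index bookkeeping for mixed
populations is easy to get wrong), and the theorem test — every mixture
reaching the closed form to $10^{-10}$ — guards the construction.

Internally all information is in nats; the reporting unit is bits.

## Numerical threshold optimization

`optimize_thresholds()` maximizes the exact information over cumulative
threshold positions. The $N+1$ interval masses are parameterized by a
softmax over $N$ unconstrained reals (one logit pinned at 0), optimized by
BFGS with a Nelder–Mead polish from multiple restarts (first restart at the
uniform partition, the rest random, controlled by a seed). The landscape
for a *fixed* label string is smooth and the restarts agree; the genuine
multimodality lives across label strings, which are enumerated explicitly
(all $2^N$, or only those with an ON threshold below an OFF threshold for
the enforced-overlap mode) rather than handled by the continuous optimizer.
Convergence failures are flagged on the result, not thrown. Ties among
thresholds (zero-width intervals) are allowed; the information is
continuous there.

## The optimal linear readout

`linear_readout()` fits $y = R^{-1}\sum_i w_i n_i + w_0$ by minimizing the
exact MSE
$E = w^\top C w - 2 U^\top w + \langle (s-w_0)^2\rangle$, where
$C_{ij} = \langle a_i a_j \rangle + \delta_{ij}\langle a_i\rangle/R$
collects activation overlaps plus the diagonal Poisson penalty. All
first/second partial moments of the built-in stimulus families (Laplace,
asymmetric Laplace, uniform, truncated power law, Gaussian) are closed
form, so no quadrature appears in the solvers.

*Noiseless* ($R = \infty$): the stationarity conditions are the Lloyd–Max
quantizer — weights are differences of interval centers of mass, thresholds
midpoints of neighboring centers. The thresholds are the same for every
ON/OFF mixture; only the offset moves (an OFF cell's weight is the negated
homogeneous weight, with the constant re-absorbed). Plain Lloyd iteration
is monotone but only linearly convergent, with rate approaching 1 as $N$
grows; after ten stabilizing sweeps the solver therefore switches to Newton
steps on the stationarity system (tridiagonal Jacobian), accepting a step
only if it does not increase the MSE. $N = 512$ converges in ~20
iterations this way. The MSE is accumulated as summed within-interval
variances rather than $\langle s^2\rangle - \sum_i m_{1,i}^2/m_{0,i}$,
which avoids catastrophic cancellation at large $N$.

*With noise*: the solver alternates (a) an exact joint solve for
$(w_0, w)$ from the augmented normal equations (the offset is treated as a
virtual always-active neuron, which is equivalent to the separate offset
equation), and (b) the threshold update
$\theta_i = (f_+ + f_-)/2 + w_i/(2R)$, where $f_\pm$ are the decoder values
on either side of the threshold. The $w_i/(2R)$ shift follows from
differentiating the exact MSE and reduces to the noiseless midpoint rule as
$R \to \infty$. Thresholds are re-sorted each iteration and nudged
apart by $10^{-12}$ if they collide (a colliding pair makes $C$ singular);
if a step increases the MSE the update is damped by halving (relevant when
$R < 1$ makes the $1 - R^{-1}$ factor negative). Convergence is declared at
a relative MSE change below $10^{-10}$, capped at $10^4$ iterations, with
non-convergence flagged. The full cross-covariance is always used, so
overlapping (non-optimal) configurations evaluate exactly too;
block-diagonality for non-overlapping solutions is then automatic rather
than assumed.

All iterative solvers start from the infomax equal-mass partition, which
sat inside the basin of attraction in every configuration exercised by the
test suite.

## Large-population threshold laws

Without noise the large-$N$ thresholds equalize the area under $p^{1/3}$
(companding); `qstim_compressed()` is closed form for all built-in
families, and for the symmetric Laplace gives $\theta(x) = 3\log 2x$ below
the median — three times the infomax (histogram-equalizing) quantile.

With noise, the package derives the asymptotic laws from the two
local stationarity conditions of the analytic MSE. Writing $w(\theta)$ for
the local weight/spacing and $T(\theta)$ for the stimulus mass of the
response region, the bulk condition is
$T \, \mathrm{d}w/\mathrm{d}i = \tfrac12 p w^2$, giving a threshold density
$\propto \sqrt{T(\theta)}$ below the mode and
$\propto \sqrt{A_+\tau_+}\, e^{-\theta/2\tau_+}$ in the upper tail — a
linear-then-logarithmic threshold profile. The first-threshold anchor comes
from the offset stationarity: for a homogeneous population it yields
$\theta_1 \approx \tau_-\log[\log(RN A_-\tau_-)/(RN A_-\tau_-^2)]$, and for
a mixed population the ON and OFF branches must carry matching
weight-times-mass at the junction, $w_{ON} T(\phi) = w_{OFF} F(\phi)$,
which closes the scalar equation
$$X(\phi) = \frac{2\tau_- F(\phi)}{\sqrt{T(\phi)}\left[\int_\phi^0
\sqrt{T(u)}\,du + 2\tau_+\sqrt{A_+\tau_+}\right]}$$
solved by `first_threshold_mixed()` for the common first threshold $\phi$
given the OFF-to-ON ratio $X$. Three facts validate the re-derivation: it
reproduces the known OFF-branch law
$\theta(x) = \phi + 2\tau_-\log(x/f_{OFF})$ exactly; it gives
$\phi(1) = 0$ and $\phi(1/4) = -0.79$ for the symmetric Laplace; and the
resulting threshold functions track the full numerical solver at $N = 100$,
$R = 1$ to a mean absolute deviation $\lesssim 0.1$ stimulus units, with
the anchor $\theta_1$ within $0.02$ of the solver's first threshold. The
mixed form assumes at least as many ON as OFF cells; the all-OFF case is
handled by mirror symmetry, and other families are directed to the
numerical solver.

## Synthetic data and what the tests do (and do not) show

The simulator draws raw Poisson counts (not pre-binarized responses) so the
$1/R$-normalized decoder is simulated faithfully; binarization happens at
analysis time. The activation convention is half-open — ON active at
$s = \theta$, OFF not — a measure-zero choice fixed for bit-reproducibility.
All stochastic outputs are deterministic functions of (inputs, seed), and
seeding is local: the caller's RNG state is restored.

The synthetic threshold generator draws i.i.d. values from a truncated
power law by inverse-cdf sampling. Its defaults emulate the pooled
dose-response threshold sets reported for larval olfactory receptor
neurons: density exponent $-0.58$, upper cutoff $4.22\times 10^4$
(concentration units), and a lower cutoff of 1, fixed once as the natural
unit concentration. The power-law
fit is OLS on the log-log cumulative of inverse thresholds, restricted to
survival probabilities in $[0.3, 0.99]$: the finite cutoffs curve the
log-log cumulative at the small-survival end, and this window keeps the
recovery bias below $0.01$ for exponents of the measured magnitude while a
truncated-Pareto maximum-likelihood fit is reported alongside as a
cross-check. Shallow exponents (cumulative slope magnitude $\lesssim 0.1$)
over few decades are intrinsically poorly identified by either method.

Passing tests on these synthetic sets show that the estimator chain
(generate → fit → invert) is self-consistent at $n = 10^5$; they do not
show that real measured thresholds follow a power law, that real ORN
populations are optimal, or that the estimator is unbiased for small
heavily-censored samples.

## Problem sizes and runtime choices

The test suite exercises: exact/recursive information up to $N = 6$ with
property tests over 40 random profiles; the Equal Coding Theorem at
$N = 4$, $R \in \{0.1, 1, 10\}$; full label enumeration up to $N = 5$;
noiseless decoders up to $N = 512$; noisy decoders and OFF-fraction sweeps
at $N = 100$ (with $N = 40$ for the finer-grained property checks); and
Monte-Carlo validation with $2\times 10^4$–$10^5$ trials. These sizes were
chosen so the full suite completes in a few minutes while every asymptotic
claim is probed in a regime where it is already accurate; all of them are
plain function arguments and scale up unchanged.
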