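---
title: "Branching-process methods in gwbranch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branching-process methods in gwbranch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwbranch)
```

## The model

A Galton–Watson process follows a population over discrete, non-overlapping
generations. Every individual alive in generation $t$ independently draws an
offspring count from a fixed law $f_k = \Pr(X = k)$, and the draws sum to
$Z_{t+1}$. The analysis is anchored on the probability generating function

$$G(s) = \sum_{k \ge 0} f_k s^k, \qquad 0 \le s \le 1,$$

whose derivatives at 1 give the offspring mean $\mu = G'(1)$ and variance
$\sigma^2 = G''(1) + \mu - \mu^2$. Two assumptions do all the work: the law
is the same for every individual and constant in time, and individuals
reproduce independently. Everything in the core modules is exact under
those assumptions; the finite-population module exists precisely because
small diploid populations violate the second one.

Four law families are supported. The empirical family is a finite PMF on
$0..k_{\max}$, the natural container for field data ("of 100 monitored
queens, 50 left no reproducing daughter..."). Poisson reproduction
($G(s) = e^{\lambda(s-1)}$) is the classical choice for modelling mutant
fates and epidemic spread; the geometric law (mean $R$, support from 0,
$G(s) = p/(1-(1-p)s)$ with $p = 1/(1+R)$) and the negative binomial
($G(s) = (p/(1-(1-p)s))^r$) express overdispersed reproductive success —
many individuals leave nothing, a few leave many. All parametric PGFs are
closed-form, never truncated series. The negative binomial has no
closed-form extinction probability and is handled entirely through numeric
PGF evaluation.

## Extinction probability

$Q$ is the smallest non-negative root of $Q = G(Q)$. The solver iterates
$q \leftarrow G(q)$ from $q_0 = 0$: because $G$ is nondecreasing and convex
on $[0,1]$, the iterates increase monotonically and converge to the
*smallest* fixed point, so root selection is by construction rather than by
enumerating polynomial roots (the test suite still cross-checks the
degree-5 case against `polyroot()`). The iteration stops when successive
iterates differ by less than `tol` (default `1e-14`, near the double-
precision floor for values of order 1; the residual $|Q - G(Q)|$ is
reported and is required to be below `1e-12`).

Closed forms are dispatched when available: supercritical Poisson uses
$Q = -W_0(-\lambda e^{-\lambda})/\lambda$, and the geometric law uses
$Q = \min(1, 1/R)$. $W_0$ is implemented directly: a fourth-order series in
$p = \sqrt{2(ez+1)}$ near the branch point $z = -1/e$ (returned as-is when
$p < 10^{-4}$, where the series error is far below machine precision) and a
Halley iteration elsewhere, converging to $10^{-15}$ relative in a handful
of steps. The branch-point series matters practically: weakly supercritical
laws ($\lambda = 1 + s$ with small $s$) put $z$ within $10^{-5}$ of the
branch point, exactly where naive Newton iteration degenerates. Tests
verify the round trip $w e^w = z$ to $10^{-13}$ relative across the domain
and agreement with an independent library implementation.

Two regime edge cases are handled explicitly. A critical law
($\mu = 1$, $\sigma^2 > 0$) short-circuits to $Q = 1$, because fixed-point
convergence at criticality is sublinear ($1 - q_t \sim 2/(\sigma^2 t)$).
The degenerate critical law $\Pr(X = 1) = 1$ is the one case where
"critical implies certain extinction" fails: the population stays at size 1
forever and the smallest root of $Q = Q$ is 0, which is what the solver
returns.

## Extinction time

The iterates $q_t$ give the extinction-time PMF
$\Pr(T = t) = q_t - q_{t-1}$, and the conditional moments divide by $Q$:

$$E(T \mid \text{ext}) = \frac{1}{Q}\sum_t t\,(q_t - q_{t-1}), \qquad
  \operatorname{Var}(T \mid \text{ext}) = E(T^2 \mid \text{ext}) - E(T \mid \text{ext})^2.$$

Under subcriticality $Q = 1$ and the equivalent survival-function forms
$E(T) = \sum_{t\ge0}(1 - q_t)$ and $E(T^2) = \sum_{t\ge0}(2t+1)(1 - q_t)$
are computed as well; the implementation warns if the two routes disagree
beyond $10^{-6}$ relative, and the test suite asserts their agreement on a
subcritical grid.

**Truncation rule.** The iteration stops when the increment falls below
$10^{-12}\max(Q, 10^{-3})$. The remaining tail is then added analytically:
near the fixed point the increments contract geometrically with factor
$c = G'(Q) < 1$, so $\sum_{k\ge1}(T_{\max}+k)^j c^k p_{T_{\max}}$ has a
closed form for $j = 0, 1, 2$. With the correction, the reported moments are
insensitive to the exact stopping generation; the bookkeeping identity
$\sum_t \Pr(T = t) + \text{tail\_mass} = Q$ holds to $10^{-10}$ by
construction and is tested.

At criticality the conditional mean diverges; the distribution object is
returned with a `divergent` flag and `NA` moments rather than a silently
large number, and the moment accessors raise an error. When
$\Pr(X = 0) = 0$ extinction is impossible, $Q = 0$, and the conditional
moments are undefined (`NA`). Interval summaries are deliberately left to
exact PMF quantiles (`quantile()` on the distribution object) rather than a
mean-plus-multiple-of-variance recipe, whose units do not match.

## Population-size distributions

The PGF of $Z_t$ is the $t$-fold composite $G_t(s) = G(G_{t-1}(s))$, and
its power-series coefficients are $\Pr(Z_t = m)$. The composition is done
on coefficient vectors: powers of $G_{t-1}$ are built incrementally
(one polynomial multiply per $k$, not binary exponentiation — simplicity
wins at the package's scale, where finite-law supports stay at
$k_{\max}^t \le 15{,}625$ for $t \le 6$) and combined with weights $f_k$.

Polynomial products are direct shift-and-add convolutions, not FFT. This is
a correctness decision, not a performance one: FFT convolution carries
absolute rounding noise around $10^{-17}$, which obliterates genuinely tiny
coefficients, while the direct sum of non-negative products preserves them —
the all-maximal-offspring coefficient $\Pr(Z_3 = 125) = 10^{-31}$ for a
degree-5 law is reproduced exactly and asserted as a ratio in tests.
Coefficients more negative than $-10^{-15}$ are an error; tiny negative
round-off above that floor is clamped to 0.

Truncation at `max_size` (required for parametric laws, optional for finite
ones; the finite-law default keeps full support up to a 32,768 cap) leaves
every retained coefficient a lower bound and tracks the deficit in
`tail_mass`, so `tail_probability()` can include it and total mass is
conserved to $10^{-12}$. The zero coefficient is unaffected by truncation
(it is exactly $G_t(0) = q_t$), which the tests exploit as a two-route
consistency check against `iterate_q()` at $10^{-10}$.

## Small diploid populations

A new allele B in a diploid population of size $N$ violates branching-
process independence as soon as BB homozygotes matter. Two exact treatments
are provided.

**Wright–Fisher chain.** Allele counts $0..2N$ form a Markov chain with
binomial resampling rows; 0 and $2N$ are absorbing. Fixation probabilities
solve the standard linear system (equal to $i_0/2N$ under neutrality, which
doubles as a $10^{-10}$ regression check), and conditional mean absorption
times use the conditioned-chain method: with $Q$ the transient block and
$h$ the vector of target-absorption probabilities, $w = (I-Q)^{-1}h$ gives
$E(T \mid \text{target}) = w_{i_0}/h_{i_0}$. Dense `solve()` is entirely
adequate at $2N+1 \le 33$ states. An independent route — propagating the
transient mass and summing $t \cdot \Pr(\text{absorb at } t)$ to horizon
3000 — agrees to $10^{-8}$ in tests, and a direct Monte Carlo of the chain
agrees within three standard errors. The diffusion-limit approximations
$\bar t_{\text{fix}}(p) = -(4N/p)(1-p)\ln(1-p)$ and
$\bar t_{\text{loss}}(p) = -4N\,\tfrac{p}{1-p}\ln p$ are provided for
comparison; their relative gap to the exact chain shrinks from $N = 1$ to
$N = 16$, as tested.

**Selfing individual.** With a single selfing AB parent producing exactly
one offspring per generation, an AA offspring means loss, BB means fixation,
AB restarts the process, so $Q = P_{AA}/(1 - P_{AB})$ — no PGF needed, and
the neutral Mendelian case gives $Q = 0.25/(1-0.5) = 0.5$ exactly. Selection
can act only in the haploid phase; the frequency shift
$\Delta p = -s\,p(1-p)/(1 + s(1-p))$ is applied independently to both
gametes, so genotype frequencies are Hardy–Weinberg at the post-selection
gamete frequency. This independent-gamete choice is a modelling decision;
it is the one consistent with selection acting on the gamete pool before
random union.

## Inference

The ratio estimator $\hat\lambda = \sum_{i\ge1} Z_i / \sum_{i\le n-1} Z_i$
is the MLE of the offspring mean for Poisson reproduction given observed
census totals; it is scale-invariant and recovers the truth within 1% in
median over 200 simulated four-generation trajectories from $Z_0 = 10^5$
(tested). Founding time is estimated by inverting expected conditional
growth, $\hat n = \ln((1-Q)Z_{\text{final}} + Q)/\ln\hat\lambda$, reported
unrounded and defined only for $\hat\lambda > 1$.

Fertility tables that aggregate a final "$K$+" category are fitted by
censored maximum likelihood: the top bin contributes
$\Pr(X \ge K) = 1 - F(K-1;\lambda)$ to the log-likelihood, maximized with
`optimize()` at tolerance $10^{-10}$ on $(10^{-8}, \max(50, 10\bar k))$.
The method recovers $\lambda$ to $10^{-6}$ from exact Poisson bin masses
for $\lambda \in \{0.5, 1, 2, 3\}$ and $K \in \{4,5,6\}$. A least-squares-
on-bin-probabilities alternative sits behind `method = "least_squares"`;
the two differ at the few-percent level on real rounded tables, which is
why the censored MLE is the default and published single-number fits are
treated as soft anchors only.

## The simulator

`simulate_gw()` is the package's independent oracle: it implements the
defining dynamics directly (every individual draws independently), so
agreement between the simulator and the analytic modules checks both. Exact
superposition identities keep it fast without changing the law: a Poisson
generation total is a single Poisson draw with mean $\lambda Z_t$, and
geometric/negative-binomial totals are single negative-binomial draws;
empirical laws draw a whole generation's offspring counts in one vectorized
sample (chunked near $10^7$ draws) and aggregate per replicate.

Determinism is part of the contract: a fixed `seed` reproduces the
trajectory matrix byte for byte (tested), and the CLI refuses to simulate
without one. Trajectories exceeding `size_cap` ($10^7$ by default) are
frozen at the cap and flagged; supercritical questions are
extinction-or-escape, and a population at the cap never returns to zero on
any horizon of interest, so capping does not bias extinction statistics.
The simulator emulates exactly what the analytic theory assumes — constant
law, independence, discrete generations. It does not emulate features of
real censuses (observation error, immigration, density dependence,
correlated or time-varying reproduction), so passing Monte Carlo checks
validate the mathematics, not the fit of the model to any particular field
system.

Test problem sizes were chosen so the whole suite runs in well under a
minute of simulation time while keeping binomial 99% acceptance bands
tight: 10,000 replicates for extinction fractions, 20,000 for conditional
extinction-generation means, 50,000 for extinction curves and the
generation-2 histogram (total-variation tolerance 0.01).

## Numerical choices, in one place

- Empirical PMFs off 1 by at most $10^{-6}$ are renormalized with a warning
  (published tables are rounded); larger deviations are hard errors. After
  renormalization the stored probabilities sum to 1 within $10^{-12}$.
- PGF evaluation outside $[0,1]$ is rejected; no caller needs it and the
  restriction keeps parametric closed forms safely inside their radius of
  convergence.
- Criticality classification uses an equality tolerance of $10^{-12}$ on
  $\mu$.
- Fixed-point tolerance $10^{-14}$ (extinction), iterate tolerance
  $10^{-12}\max(Q, 10^{-3})$ with analytic geometric-tail correction
  (extinction time), coefficient clamp floor $-10^{-15}$ (size
  distributions).
- Dense linear algebra throughout the Wright–Fisher module; all supported
  cases are tiny, and `N` beyond a few hundred would call for sparse or
  iterative methods the package deliberately omits.

## Limitations

Single-type processes only: no multi-type lineages, dormancy switching,
parent–offspring correlation in reproductive success, overlapping
generations, or continuous time. Selection and dominance inside the
Wright–Fisher diploid chain are out of scope (the chain is neutral; the
selfing model covers the one-individual selected case). Confidence
intervals for $\hat\lambda$ are not provided. The geometric/negative-
binomial families assume support starting at 0; laws shifted to start at 1
must be supplied as empirical tables.
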