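---
title: "Distance-based copy-number analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based copy-number analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvdist)
```

## The distance-type representation

Conventional read-depth analysis of whole-genome DNA sequencing summarizes
coverage as read counts in fixed-width windows, which requires choosing a
window size and discards within-window information. `cnvdist` instead works
with the *distances* between adjacent mapped reads: for sorted
first-aligned-base positions $s_1 \le s_2 \le \dots \le s_m$ on a
chromosome, the data are the $m - 1$ gaps $y_i = s_{i+1} - s_i$ (in bp).
Under a copy-number deletion the local read density halves and the local
gaps double, so distances carry the same signal as counts without any
windowing decision. Two reads starting at the same position give $y = 0$,
which the model's support allows.

Some genomic regions (centromeres, unmappable sequence) produce extremely
large gaps that no coverage model should be asked to explain. These are
handled by *artificial right censoring*: given a constant $T$, a gap is
kept as an exact value only if $y \le T$; larger gaps are recorded only as
"greater than $T$" ($\delta = 0$). The default $T = 5000$ bp censors on the
order of 1–3% of gaps at cell-line-like coverage. Note the boundary
convention: censored means *strictly greater* than $T$, which is the only
convention under which the censored distribution below sums exactly to one.

## The censored-geometric mixture model

A single coverage regime is modelled by a geometric distribution on
$\{0, 1, 2, \dots\}$ (failures before the first success; memoryless, the
discrete analogue of the exponential waiting time): each base pair is the
start of a read with probability $p$. With right censoring at $T$ the
probability function of one observation $(y, \delta)$ is

$$f(y) = \left(p (1-p)^y\right)^{\delta}
         \left((1-p)^{T+1}\right)^{1-\delta},$$

where $(1-p)^{T+1} = P(Y > T)$ is the censored mass. A chromosome mixes
regions with different biological properties and hence different read
densities, so the working model is a $g$-component mixture
$f(y) = \sum_{j=1}^g \pi_j f_j(y)$ with proportions $\pi_j$ and
per-component success probabilities $p_j$.

Sequencing depth also depends on local GC content. The GC adjustment
extends each component to a generalized linear model in the window GC
fraction $x$ through the log-mean link

$$\mu_j = \frac{1 - p_j}{p_j}, \qquad
  \eta_j = \log \mu_j = \beta_{j0} + \beta_1 x,$$

with the slope $\beta_1$ *shared* across components: the GC effect is a
property of the sequencing chemistry and reference genome, not of any one
coverage regime. The proportions likewise do not depend on $x$. Components
are always stored in canonical order (mean distance increasing, i.e. $p$
decreasing or $\beta_{j0}$ increasing) so that fits are comparable across
runs despite EM label switching.

## Estimation

`fit_mixture()` and `fit_mixture_glm()` maximize the observed-data
log-likelihood by EM. The E-step computes responsibilities
$\tau_{ij} \propto \pi_j f_j(y_i; x_i)$ in log space. The M-step updates
$\pi_j = \sum_i \tau_{ij} / n$ and, for the plain mixture, uses the
closed-form weighted maximum-likelihood update

$$\hat p_j = \frac{\sum_i \tau_{ij}\,\delta_i}
  {\sum_i \tau_{ij}\left[\delta_i (1 + y_i) + (1-\delta_i)(T+1)\right]},$$

which zeroes the derivative of the weighted complete-data log-likelihood.
For the GLM the coefficient vector $\beta = (\beta_{10}, \dots, \beta_{g0},
\beta_1)$ has no closed form; writing $a_i = \delta_i y_i +
(1-\delta_i)(T+1)$ and $b_i = a_i + \delta_i$, each component's log-density
in the link scale is $a_i \eta - b_i \log(1 + e^{\eta})$, with first
derivative $a_i - b_i(1-p)$ and second derivative $-b_i\,p(1-p)$. The
$\tau$-weighted Hessian is therefore negative semi-definite everywhere, and
the M-step runs damped Newton-Raphson steps
$\beta \leftarrow \beta + (X^\top W X)^{-1} X^\top s$ (intercept-indicator
plus covariate design, $W = \tau b p (1-p)$, $s = \tau(a - b(1-p))$) with
step halving, iterated to stationarity (capped at 25 inner iterations).
The analytic score is verified against central finite differences in the
test suite.

Numerical choices that matter:

* **Initialization** (not determined by the model): distances are split
  into $g$ groups by quantiles of $\log(1+y)$ and each group's geometric
  MLE seeds a component. `n_restarts` (default 5) jittered restarts guard
  against local optima; the best final likelihood wins.
* **Convergence**: relative change in the log-likelihood below `tol`
  (default 1e-8) or 500 iterations.
* **Boundaries**: $p_j$ clamped to $[10^{-12}, 1-10^{-12}]$, proportions
  floored at $10^{-8}$ and renormalized; a component whose proportion
  falls below $10/n$ triggers a collapse warning, and a component with no
  uncensored weight is an error.
* The plain-mixture EM loop is compiled (Rcpp); a pure-R reference
  implementation is kept and the two are cross-checked in the tests.

**Pseudo-maximum likelihood for tumor/normal pairs.** Because GC content
is computed from the reference genome, the GC slope estimated on the
normal sample is carried over and *fixed* (`fixed_beta1`) when fitting the
matched tumor sample; only the tumor's intercepts and proportions are
re-estimated. `run_pipeline()` wires this protocol end to end.

## Choosing the number of components

Likelihood-ratio tests between mixtures with different component counts
have no valid chi-square reference (the null sits on the boundary of the
alternative's parameter space), so `bootstrap_component_test()` uses a
parametric bootstrap: fit both $g_0$ and $g_1$, simulate $B$ datasets from
the fitted $g_0$ model (same $n$, same $T$; in GLM mode conditioning on
the observed covariates, which are fixed genome properties), refit both
models per replicate, and report
$p = (1 + \#\{\mathrm{LRT}_b \ge \mathrm{LRT}_{\mathrm{obs}}\})/(B+1)$ —
a convention that cannot produce an exact zero. Two design points:

* The alternative fit additionally warm-starts from a split-component
  perturbation of the null fit, making the nested ordering
  $l_1 \ge l_0$ reliable without reusing observed-data fits across
  replicates (replicate refits stay cold in that sense).
* The observed-vs-bootstrap comparison ranks the *raw* differences
  $2(l_1 - l_0)$. The null distribution of the component-test LRT has
  substantial mass within optimizer noise of zero; flooring both sides at
  zero before ranking would convert that mass into exact ties and pile
  null p-values onto 1. Ranking raw values preserves exchangeability; the
  *reported* statistics are still floored at zero. With this convention
  the null p-values are uniform (checked by simulation in the test
  suite: 200 repetitions of the 3-vs-4 test at $B = 99$).

## From distances to z-values

With a fitted model, each uncensored distance is transformed by the
mixture CDF $F(y; x) = \sum_j \pi_j F_j(y; x)$ followed by the
standard-normal quantile function: $z = \Phi^{-1}(F(y; x))$. If the model
fits, this is a probability integral transform and the z-values are
approximately standard normal *and* free of the GC trend, since $x$ enters
the CDF. Three caveats the tests make explicit:

* The geometric is discrete, so the PIT is exact only up to the pmf atom
  sizes; a mid-p variant would tighten this but $F(y) = P(Y \le y)$ is
  used directly by default (mid-p available via the rank-based
  alternative's machinery is deliberately *not* silently substituted).
* Censored distances have no exact value; they are assigned a fixed
  sentinel $z = 10$ (larger than any achievable finite z, enforced at
  transform time). Sentinels are retained in outputs and plots but are
  excluded from all downstream test statistics and likelihoods — a
  constant 10 would poison block means.
* Because only uncensored values are transformed, the finite z are
  truncated at $\Phi^{-1}(F(T))$: their KS distance from normal floors at
  roughly the censored fraction. At the 1–3% censoring the default $T$
  targets, this is well below the scale of copy-number shifts.

A rank-based (Blom) transform is available as a labelled alternative
(`rank_based = TRUE`); it enforces normality by construction but forfeits
the GC adjustment, so the model-CDF transform is the primary path.

## Change-point segmentation

z-values are grouped into fixed-width bins (default 50 kb, half-open
intervals on the left-read anchor) and segmented by *recursive
combination*, an agglomerative procedure: starting from one block per bin,
each round computes a pooled-variance two-sample t-test for every adjacent
block pair; among pairs with $p > \alpha_C$ it applies the merge that
maximizes the overall Gaussian likelihood (block means, one pooled
variance, leftmost pair on ties), and it stops when every adjacent pair
differs at level $\alpha_C$. The per-comparison level is Bonferroni-style,
$\alpha_C = 0.05 / (m(m-1)/2)$ for $m$ bins, computed on the retained
(non-empty) bins. The pooled t-test is the likelihood-ratio-consistent
choice for the equal-variance Gaussian model used in the merge criterion;
the near-normality of the z-values (checkable with `qq_check()`) is what
licenses Gaussian rather than permutation p-values. Degenerate
comparisons (too few values for a t-statistic) count as mergeable; a
zero-variance comparison with unequal means counts as separated.

## The synthetic read generator and what it does (not) show

`simulate_region_reads()` generates read start positions as a renewal
process: cumulative sums of gaps drawn from a censored-geometric mixture,
truncated to the region. The default gap model (`default_gap_model()`)
has three components with a mean gap of roughly 1.3 kb, chosen to match
the coverage implied by the application-style fitted model used elsewhere
in the test suite. Deletions are emulated by independent 50% read
thinning (`thin_reads()`), halving density and doubling mean gaps.

The benchmark experiments (`detection_power_experiment()`,
`detection_accuracy_experiment()`) compare the distance representation
against windowed counts with the two-sample KS test, scanning all
admissible change locations (a guard band of 5 observations per side
avoids degenerate KS comparisons; splits are ranked by the scaled KS
statistic, which orders identically to the asymptotic p-value but cannot
underflow to tied zeros). Non-detections enter the rank-sum accuracy
comparison at a sentinel worse than any observed error.

The generator reproduces the *structure* of real read tracks (renewal
gaps, mixed coverage regimes, thinned deletions) but not their local
irregularities: mappability holes, PCR duplicates, GC waves along the
genome, or the empirical gap distribution of any particular cell line.
Consequently the benchmark validates qualitative orderings — power
increasing with region length, distance-type localization beating
count-type at short lengths and stringent cutoffs, nominal type-I control
— not any particular published percentage. One such ordering is
one-sided by nature: the count pipeline's KS test runs on small samples
of tied integers and is therefore conservative under the null, so its
type-I error is bounded by, not equal to, the nominal level.

## Simulation scales used in the test suite

Statistical checks run at sizes chosen to balance power against runtime
on a single CPU: parameter recovery uses 200 replicates at $n = 5000$
(means within ±0.02 of the true proportions, ±20% relative on success
probabilities) with RMSE monotonicity checked across
$n \in \{100, 250, 500, 1000, 5000\}$; the near-one bias check uses 200
replicates at $n = 1000$; bootstrap-LRT calibration uses 200 repetitions
of the 3-vs-4 test with $B = 99$ at $n = 200$; benchmark orderings use
120–300 repetitions per setting. Tolerances on stochastic checks are set
at 2–3 standard errors of the quantity under test.

## Known limitations

* Single-end logic only: paired-end reads are treated by their leftmost
  aligned position.
* One covariate (GC); proportions independent of it by design.
* No standard errors on fitted parameters; the bootstrap test addresses
  only the component count.
* Segment means are reported in z-units; calling integer copy numbers
  from them is out of scope.
* Estimates of success probabilities near 1 (a component of near-zero
  gaps) are biased downward in the median at moderate $n$ — reproduced
  deliberately in the test suite; be cautious interpreting such
  components.
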