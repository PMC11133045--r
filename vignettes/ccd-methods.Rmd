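---
title: "Randomization tests for changing criterion designs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomization tests for changing criterion designs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccdrand)
```

## The design and the statistic

A changing criterion design (CCD) steps a performance criterion up or
down across successive intervention phases after an initial baseline.
Experimental control is demonstrated when the behavior tracks the
criterion. `ccdrand` quantifies that tracking with the mean absolute
deviation (MAD) over the $m$ intervention measurements,

$$\mathrm{MAD} = \frac{1}{m}\sum_{t=1}^{m} \lvert y_t - c(t)\rvert,$$

where $c(t)$ is the criterion of the phase containing occasion $t$.
The MAD pools over *measurements*, each occasion weighted equally, so
longer phases contribute proportionally more. The alternative — an
unweighted mean of per-phase mean deviations — coincides with this
definition when phases are equally long; the pooled version was chosen
because it reads "mean absolute deviation of the series" literally and
matches the length-weighted construction used by the no-effect data
generator (below). The baseline is excluded from both the statistic and
the randomization: it carries no criterion that its scores could be
compared against, and excluding it leaves baseline length free to be
determined by stability considerations.

The p-value of either test is one-sided and lower-tailed: the
proportion of reference assignments whose MAD is at or below the
observed one. Ties are resolved by exact `<=` comparison on binary
floating point; the observed statistic is always computed through the
same code path as the reference distribution (segment-wise cumulative
sums for PCM, the order-by-occasion matrix for BAC), so exact ties are
reproducible and no epsilon is needed. Under systematic enumeration the
observed assignment is a member of the reference set, so $p \ge 1/R$
and $p$ is always a multiple of $1/R$.

## Phase-change-moment (PCM) randomization

PCM fixes the order of the criterion levels (first criterion to the
first segment, and so on) and randomizes the phase-change occasions.
With $m$ measurements, $I$ phases, and phase lengths constrained to
$[k_{\min}, k_{\max}]$, the admissible assignments are the bounded
integer compositions of $m$ into $I$ parts. With a non-binding maximum
the count has the closed form
$\binom{m - I k_{\min} + I - 1}{I - 1}$; in general the package counts
by dynamic programming over (remaining sum, remaining phases). The
default maximum is $m - (I-1)k_{\min}$, the largest any phase can be
when all others sit at the minimum, which never binds.

Three operations are built on the same count table:

* **Enumeration** lists each composition exactly once in lexicographic
  order (first phase varying slowest), so reference distributions are
  bit-reproducible. Enumeration is refused above a configurable cap
  (default $10^6$) with a pointer to Monte Carlo mode.
* **Uniform sampling** draws each phase length with probability
  proportional to the number of completions of the remaining phases.
  This is exact uniform sampling without rejection — important because
  feasible compositions can be a vanishing fraction of all bounded
  tuples (for 15 measurements in four phases of length 3–6, only 20 of
  the $4^4 = 256$ tuples have the right total).
* **The test** computes the reference MADs for all (or a sampled set
  of) compositions via per-criterion cumulative sums of
  $\lvert y_t - c_i \rvert$, which makes each composition an $O(I)$
  lookup rather than an $O(m)$ scan.

In Monte Carlo mode the sampled compositions are i.i.d. uniform (with
replacement), and the observed assignment is added to the reference
set: $p = (1 + \#\{\text{sampled MAD} \le \text{observed}\})/(B + 1)$
for $B$ samples. Including the observed assignment guarantees validity
of the Monte Carlo test; with 1000 samples the smallest attainable
p-value is $1/1001$.

## Blocked-alternating-criterion (BAC) randomization

BAC fixes the phase boundaries and randomizes which of the two
criterion levels in each consecutive block of two phases comes first:
$2^B$ admissible orders for $B$ blocks, always enumerated exactly.
Under a swap the criterion levels move across the block's two segments
while the segment lengths stay attached to their positions — phase
lengths in BAC are typically determined response-guidedly and are not
part of the randomization. Blocks are always consecutive,
non-overlapping pairs in temporal order; an odd number of intervention
phases is an error (blocks of three are not supported). Below five
blocks the smallest attainable p-value exceeds .05, so the test warns
below ten phases.

## The simulation model

`simulation_condition()`, `estimate_rejection_rate()` and
`run_condition_grid()` implement a Monte Carlo engine for type I error
and power. Its data-generating model:

* **Criterion staircase.** Criteria rise from a baseline level
  (default 10) in fixed increments (default 5):
  $c_i = \text{baseline} + i \cdot \text{increment}$. With
  `reversal = TRUE` (requires at least four phases) the penultimate
  phase steps back one increment below its predecessor and the last
  phase resumes one increment above it — a *mini-reversal* to a less
  stringent criterion, e.g. `15 20 15 25` for four phases. Among the
  readings compatible with "step back, then increase again", the
  resume-the-staircase rule was chosen and is configurable through
  `build_criteria()`.
* **Noise.** Gaussian, serially dependent: a single stationary AR(1)
  stream $z_t = \phi z_{t-1} + u_t$ spans the whole series
  (dependence is not reset at phase changes), with innovations scaled
  by $1-\phi^2$ so the marginal variance is 1 for every $\phi$. The
  noise scale is *criterion-proportional*: in effect conditions
  $y_t = c(t) + v\, c(t)\, z_t$ with variability proportion $v$
  (typical grid .10, .25, .50), so more demanding phases are noisier.
  Keeping the marginal (not innovation) standard deviation at
  $v \cdot c(t)$ means power comparisons across $\phi$ reflect
  dependence, not inflated variance. Gaussian noise is the standard
  choice in the single-case simulation literature; nothing in the
  procedures requires it, and `generate_ar1()` is the single point
  where another distribution could be substituted.
* **No-effect data.** Flat series at the length-weighted mean of the
  criterion levels, $L = \sum_i \ell_i c_i / m$ (the simple average
  for equal lengths), with constant noise scale $v \cdot L$. The
  criterion labels are retained, so the test confronts flat data with
  a staircase of criteria — the standard way of probing type I error.
* **Actual assignments.** In every replicate the BAC actual order is
  drawn by a fair coin per block. For PCM the actual composition is
  either fixed to a deterministic pattern — `uniform`, `increasing`
  (minimum 3 first, surplus spread over later phases, remainders
  last), `triangular` (ends at 3, surplus round-robin from the middle
  outwards) — or drawn uniformly from the admissible set
  (`lengths = "random"`). Patterns mirror how applied CCD series look;
  the uniform-random option supports exactness checks.
* **Estimates.** The rejection rate at $\alpha$ (default .05) over
  `replications` (default 1000) generate-and-test cycles, with its
  binomial standard error. PCM reference distributions are systematic
  up to the enumeration cap and Monte Carlo (1000 samples) beyond.
  Grids derive one RNG substream per condition from the master seed by
  a fixed counter scheme, so results are reproducible and individual
  conditions can be rerun alone.

### A note on exactness and the no-effect level

The randomization-test validity guarantee requires the data to be
generated independently of the actual assignment. The no-effect
generator satisfies this for BAC with equal phase lengths (the level
$L$ is invariant under within-block swaps), and for PCM whenever the
actual composition is fixed, as it is under the patterns. If instead
the actual PCM composition is drawn uniformly per replicate *and* the
level is the length-weighted average of that drawn composition, the
data are correlated with the assignment and the empirical type I error
rises to roughly .067 at $\alpha = .05$ in a 20-measurement, 4-phase
design — a small but real liberality worth knowing about when planning
response-guided variants. With the pattern-fixed actual composition
the same design yields rates near .005, i.e. the test is conservative,
as coarse reference sets with a lower-tail statistic tend to be.

### What the simulations do and do not show

The generator emulates criterion-tracking behavior with
level-proportional, serially dependent noise. It does not emulate
within- or between-phase trends, floor or ceiling effects, integer or
bounded outcomes (scores stay continuous; no rounding), response-guided
phase lengths, or multiple tiers per participant. Conclusions from the
shipped simulations therefore speak to level-tracking under stationary
noise, not to trending data. Two model-driven regularities are worth
stating explicitly:

* Power is governed by the ratio of the criterion step to the local
  noise scale, $\text{increment}/(v \cdot c)$. Because the baseline
  level is fixed, small increments (e.g. 1 with baseline 10) produce
  criteria whose steps are fractions of the noise SD, and power drops
  sharply relative to an increment of 5. Power is only
  increment-insensitive when the criterion levels scale with the
  increment, which keeps that ratio constant.
* Mini-reversals help both procedures: they break the near-collinearity
  between a monotone staircase and flat or drifting data. For
  short-phase BAC designs the benefit is large (roughly .10–.13 in
  rejection rate at $v = .10$, $\phi = .3$); for PCM it also repairs
  the inflated type I error of triangular length patterns.

### Problem sizes

The shipped test suite and acceptance script use 1000 replications per
power condition, 2000 for type I error checks, systematic PCM reference
sets up to 3,876 compositions, and $10^5$ draws for the uniformity
check of the composition sampler; the full suite runs in well under a
minute. These sizes give binomial standard errors of .014 or less on
rates near .5 and were chosen as the package's reporting defaults;
`replications` scales them freely.

## Numerical and interface decisions

* Composition counts are held as doubles (exact below $2^{53}$, far
  beyond any enumerable design).
* Sessions in data files are validated but not used computationally;
  analysis follows row order. The baseline is recognised as the first
  phase whose `Criterion` cells are empty, with an explicit
  `baseline_label` override; missing scores are an error because
  neither procedure defines gap handling.
* Monte Carlo PCM sampling is i.i.d. with replacement; a
  without-replacement subset would complicate the validity argument
  for no practical gain at the reference sizes involved.
* `eta_squared_oneway()` and `eta_squared_interaction()` report
  variance proportions (SS effect over SS total, sequential sums of
  squares) and deliberately omit F tests; simulation grids should be
  balanced, and unbalanced input warns. `paired_t_r2()` converts a
  paired t into $r^2 = t^2/(t^2+\nu)$ for matched with/without
  contrasts (e.g. the reversal effect), with the degenerate
  zero-variance limits documented in its help page.

## Known limitations

Blocks of three criteria (odd phase counts), completely randomized
criterion orders, distributed criterion designs, response-guided
randomization and trend-aware statistics are out of scope. The BAC
test's power is capped by $2^B$; with fewer than five blocks it cannot
reject at .05 at all, and the package warns rather than refuses.
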