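---
title: "The uniform approximation to the Wilcoxon rank-sum null in gene set analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The uniform approximation to the Wilcoxon rank-sum null in gene set analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uniwrs)
```

## The problem

Competitive gene set analysis asks whether the genes in a set (a GO term, a
pathway) carry systematically larger or smaller differential-expression
statistics than the genes outside the set.  The Wilcoxon rank-sum (WRS) test
is the natural tool: pool the per-gene "local" statistics, rank them, and
compare the rank sum $W$ of the $m$ set genes against its permutation null
over all $\binom{N}{m}$ equally likely assignments, where $N = m + n$ and $n$
is the size of the complement.

At genome scale the exact null is unaffordable ($N \approx 10^4$), and the
ubiquitous fallback is the normal approximation with null mean
$\mu = m(N+1)/2$ and variance $\sigma^2 = mn(N+1-TF)/12$.  That
approximation is accurate when *both* groups are large — but gene sets are
small.  Most GO terms measured on an array have 2–8 genes, so the relevant
regime is $m \le 30$ against $n > 10^4$, and there the normal tail is far too
heavy: at $m = 3$, $N = 10^4$, the most extreme configuration possible has
exact one-sided p-value $1/\binom{10^4}{3} \approx 6.0\times10^{-12}$, while
the normal approximation reports $1.4\times10^{-3}$ — nine orders of
magnitude too large, and incapable of ever clearing a Bonferroni threshold
over thousands of terms.

## The uniform (Irwin–Hall) approximation

As $n \to \infty$ with $m$ fixed, the empirical distribution of the
complement becomes a continuum and each set gene's standardized rank behaves
like an independent uniform(0,1) draw.  The affinely standardized rank sum
therefore converges to an **Irwin–Hall** variable $S_m$, the sum of $m$
independent uniforms.  The package matches the first two moments of $W$ to
those of $S_m$ ($E S_m = m/2$, $\mathrm{var}\, S_m = m/12$):

$$
d = \sqrt{n\,(N + 1 - TF)}, \qquad
c = \frac{m(N+1)}{2} - \frac{m\,d}{2},
$$

so that $P(W \le w) \approx F_m\!\big((w - c + 0.5)/d\big)$ and
$P(W \ge w) \approx 1 - F_m\!\big((w - c - 0.5)/d\big)$, with $\pm 0.5$ the
continuity correction for the discrete $W$ (widening both tails) and $F_m$
the Irwin–Hall CDF.  $TF = \sum_i (d_i^3 - d_i) / (N(N-1))$ is the usual tie
correction over the multiplicities $d_i$ of the distinct pooled values; it
is zero without ties and enters only through the variance (no higher-order
tie adjustment is attempted, because none is defined for this limit).  The
two-sided p-value is twice the smaller one-sided value, clamped at 1 — the
same doubling rule the exact and normal back-ends use, so the three are
comparable.

This standardization reproduces every published extreme-case value the
package's acceptance tests assert (e.g. $7.15\times10^{-12}$ at $m=3$ and
$1.21\times10^{-58}$ at $m=20$, $N = 10^4$), which is the strongest check
available that the affine map is the right one.

Two asymmetries are worth knowing:

* the approximation is for the *small* group's rank sum.  Pass the gene set
  as the first group; swapping the groups replaces a sum of $m$ uniforms by
  a sum of $n$ and changes the p-value slightly (the normal and exact
  back-ends are exactly swap-symmetric, this one is only asymptotically so);
* in the far tail the uniform approximation always lies below the normal one
  for $m < 30$; the two essentially coincide once $m \ge 30$ (central limit
  behaviour of $S_m$; the maximal CDF gap at $m = 30$ is about $9\times
  10^{-4}$).  The enrichment driver's `method = "auto"` therefore uses the
  uniform back-end below 30 scored set genes and the normal one at 30+.

## Evaluating the Irwin–Hall CDF stably

The textbook formula
$F_m(u) = \frac{1}{m!}\sum_{j=0}^{\lfloor u\rfloor} (-1)^j \binom{m}{j}(u-j)^m$
is an alternating series whose terms exceed the result by many orders of
magnitude for moderate $m$: summed in double precision it cannot deliver
the $\sim 10^{-58}$ tails the application needs.  `pirwinhall()` therefore
never sums it.  Instead it uses three all-positive paths:

1. **Symmetry first.**  Only the smaller tail is ever computed:
   $F_m(u) = 1 - F_m(m - u)$ for $u > m/2$, and the survival function is
   $F_m(m-u)$ directly — never $1 - F$ — so upper tails keep full relative
   precision.
2. **Single-term region.**  For $u \le 1$ only the $j = 0$ term survives:
   $F_m(u) = u^m/m!$, evaluated in log space.  Every genome-scale deep-tail
   query lands here.
3. **B-spline quadrature elsewhere.**  The Irwin–Hall density is the uniform
   B-spline of order $m$ on knots $0,\dots,m$, which the Cox–de Boor
   recurrence evaluates with nonnegative coefficients (forward stable).  The
   CDF is its integral, taken per unit interval with Gauss–Legendre rules of
   $\lceil m/2\rceil$ nodes — *exact* for the degree-$m{-}1$ polynomial
   pieces, and a sum of positive terms, hence no cancellation at any $m$.

The test suite pins this evaluation against the alternating series where it
is stable ($m \le 8$), an independent Simpson-convolution oracle, the
closed-form tail, symmetry and monotonicity grids, and the normal limit.
Because the evaluation is stable for every $m$, no large-$m$ fallback to the
normal distribution is needed or used inside `pirwinhall()`; cost grows as
$O(m^3)$, which is negligible for gene-set sizes.

At integer $u$ the $j = \lfloor u\rfloor$ series term vanishes, so the
quadrature path (which has no branch at integers) is automatically
continuous there.

## The exact back-end

`exact_p_shift()` builds the full permutation distribution of $W$ over the
observed midrank multiset by the shift algorithm: a dynamic program over
doubled midranks (midranks are multiples of $\tfrac12$, so doubling makes
all sums integral), implemented in C++.  It is exact under ties and is the
oracle the approximations are tested against; it refuses $N > 200$ by
default because its cost, $O(N \cdot m \cdot N^2)$ in time, is the reason
approximations exist at all.  Subset counts are accumulated in doubles:
above $N \approx 180$ they exceed $2^{53}$ and are no longer exact integers,
but their $10^{-15}$ relative error is irrelevant for tail probabilities
(the full distribution still sums to 1 within $10^{-12}$, which the tests
assert).

## Local statistics

Only the *ranks* of the per-gene statistics enter the set-level test, so any
strictly monotone transform of a local statistic leaves every p-value
unchanged (a property test asserts this).  The package still ships the
statistics practitioners actually compute, so pipelines are reproducible
end to end:

* `local_t()` — pooled-variance two-sample t.  Pooled rather than Welch
  because the downstream use is rank-based and the choice is essentially
  inconsequential there; genes with zero pooled variance get statistic 0
  with a warning rather than NaN.
* `local_log2fc()` — difference of group means on the log2 scale.
* `poisson_wald()` — $z = (x - \hat t y)/\sqrt{\hat t (x+y)}$ for summed
  counts $x, y$ with library-size ratio $\hat t = T_1/T_2$; the score-type
  standardization of the rate difference, approximately N(0,1) under the
  equal-rate null (verified by simulation at $10^5$ draws).  Algebraically
  equivalent proportion-scale forms exist; this one is used throughout.
* `poisson_lr()` — the two-group Poisson likelihood ratio in closed form
  ($0\log 0 \equiv 0$), identical to the GLM deviance difference for this
  design (a test cross-checks against `glm()`), with an optional signed
  variant for one-sided set tests.

Negative-binomial likelihood ratios require a dispersion estimator and are
deliberately out of scope; `read_gene_stats()` accepts any externally
computed per-gene statistic, which covers that case.

The group-label convention is: first factor level (or alphabetically first
label) minus the second, so relabelling the samples flips every sign.

## The enrichment driver

`wrs_enrich()` intersects every set with the scored universe *before* size
filtering (genes without statistics exist for neither side of the test),
keeps sets with 2–30 scored genes by default (the window where the
approximations differ and where most GO terms live; both bounds are
arguments), computes ranks and the tie factor once for the whole universe,
and reports both `p_uniform` and `p_normal` for every set alongside the
`p_used` selected by `method`.  Multiple-testing adjustment defaults to
Bonferroni via `stats::p.adjust` and feeds on `p_used`.  Overlapping sets
are tested independently — competitive testing ignores overlap, a known
limitation, not an oversight.  Output ordering is deterministic (by
`p_used`, ties by term id), so identical inputs give byte-identical tables.

## Simulation design

The simulations draw local statistics directly per gene — no sample-level
expression is generated, no gene–gene correlation is induced.  Under the
null all $G = 15000$ statistics come from N(3, 1); the location is
arbitrary because only ranks matter, and a test asserts this invariance.

* **False positive rate** (`simulate_fpr`): per round one pool of $G$ values
  is drawn and 100 random $m$-subsets are tested (subsets of one pool, not
  fresh pools — the subsets within a round share the pool and are therefore
  mildly dependent, which is what the averaging over 50 rounds is for).
  Two-sided p-values at $\alpha \in \{0.05, 0.01, 0.001\}$.
* **Power** (`simulate_power`): per repetition a fresh universe, with the
  $m$ set statistics drawn from N(3 + $\delta$, 1); rejection at two-sided
  $p < 0.0005$ (0.05 with a Bonferroni correction of order 100).  Adding
  $\delta$ to the set rather than to the complement is equivalent in
  distribution for a two-sided test; the set-side reading is implemented.
  The two approximations are evaluated on the *same* draws, so their power
  difference is a paired comparison.

RNG: each (size, effect, round) cell derives its own seed deterministically
from the root seed, so results are reproducible and independent of
evaluation order.

The default scales are 50 rounds × 100 repetitions (FPR) and 30 × 100
(power), the scales at which the reference false-positive rates in the
acceptance script are computed.  The test suite runs reduced scales — 10×100
for calibration (tolerance three binomial standard errors at 1000 draws) and
5×60 on a coarse $(m, \delta)$ grid for the power ordering — chosen as the
smallest designs at which the assertions are decisive rather than noisy.

`make_fixture()` generates the synthetic enrichment inputs (N(0,1)
statistics, random sets, spiked sets with a mean shift of 3 by default — a
strong, unambiguous enrichment signal): it emulates a scored universe with
known truth, not real expression data.  What passing on fixtures shows is
that the machinery is correct and calibrated under independence; it says
nothing about inter-gene correlation, annotation bias, or the adequacy of
any local statistic for a particular platform, all of which affect real
data.

## Known limitations and open choices

* The published table of extreme-case p-values is read as one-sided (its
  exact row equals $1/\binom{N}{m}$, which is the one-sided value); all
  comparisons here follow that reading.
* The uniform back-end is not exactly label-swap symmetric (see above);
  always pass the gene set as the first group.
* Competitive testing treats genes as exchangeable; correlated genes make
  the nominal null anti-conservative regardless of which approximation is
  used.  This is a property of gene permutation, not of the Irwin–Hall
  evaluation.
* GO-graph propagation, annotation retrieval and expression preprocessing
  are out of scope: the package consumes per-gene statistics and gene-set
  definitions (GMT or two-column mapping) as given.
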