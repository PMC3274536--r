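# uniwrs

Competitive gene set enrichment with the Wilcoxon rank-sum (WRS) test, using
a **uniform-sum (Irwin–Hall) approximation** to the null distribution of the
rank sum.

## Why

Gene set analysis ranks per-gene differential-expression statistics and asks
whether the genes of a set (a GO term, a pathway) sit unusually high or low
among all `N` measured genes.  The WRS test is the standard competitive
test, but its exact permutation null over the `choose(N, m)` assignments is
unaffordable at genome scale, and the usual normal approximation — mean
`m(N+1)/2`, variance `mn(N+1-TF)/12` — is badly miscalibrated exactly where
gene set analysis lives: a small set (`m < 30`) against a huge complement
(`n > 10^4`).  In the most extreme configuration at `m = 3`, `N = 10^4` the
exact one-sided p-value is `1/choose(10^4, 3) ≈ 6.0e-12`, while the normal
approximation reports `1.4e-3` — nine orders of magnitude off, and unable to
pass any multiple-testing threshold.

As the complement grows, the affinely standardized rank sum of the `m` set
genes converges instead to a sum of `m` independent uniform(0,1) variables
(the Irwin–Hall distribution `F_m`).  With moment-matched constants

    d = sqrt(n (N + 1 − TF)),   c = m(N+1)/2 − m d / 2,

the package approximates `P(W ≥ w) ≈ 1 − F_m((w − c − 0.5)/d)` (and the
mirror image for the lower tail), with `±0.5` a continuity correction and
`TF` the standard tie correction `Σ(d_i³ − d_i)/(N(N−1))`.  This is accurate
down to the deepest reachable tails (`~1e-58` at `m = 20`, `N = 10^4`),
calibrated at nominal levels, and substantially more powerful than the
normal approximation for sets under 30 genes.

The numerically hard part — evaluating `F_m` without the catastrophic
cancellation of its alternating-series formula — is done with an
all-positive algorithm: Cox–de Boor evaluation of the Irwin–Hall density
(a uniform B-spline) integrated by per-interval Gauss–Legendre quadrature
that is exact for its polynomial pieces, plus tail symmetry and the
closed-form single-term region.  Details in the vignette
(`vignettes/uniform-approximation.Rmd`).

## What is in the package

* `pirwinhall()` / `dirwinhall()` — stable Irwin–Hall CDF/density.
* `wrs_test()` — the WRS test with three null back-ends: `uniform`,
  `normal` (continuity-corrected, matches `wilcox.test`), and `exact`
  (shift-algorithm permutation distribution in C++, for small `N`);
  midrank tie handling throughout; `tidy()`/`glance()` methods.
* `local_t()`, `local_log2fc()`, `poisson_wald()`, `poisson_lr()` —
  per-gene local statistics for array and RNA-seq inputs.
* `wrs_enrich()` — GMT- or mapping-driven competitive enrichment over a
  scored gene universe, reporting both approximations per set, with
  Bonferroni (or any `p.adjust`) correction; `read_gmt()`,
  `read_gene_mapping()`, `read_gene_stats()` for the file formats.
* `simulate_fpr()`, `simulate_power()`, `make_fixture()` — the simulation
  machinery comparing the approximations, and synthetic fixtures with known
  spiked-in truth; `autoplot()` views.
* `exec/uniwrs` — a thin command-line wrapper (`pvalue`, `enrich`,
  `simulate fpr|power`, `fixture`).

## Worked example

The extreme configuration: a 3-gene set ranked above all 9,997 other genes.

```r
library(uniwrs)
values <- 1:10000                      # any distinct statistics; ranks decide
fit <- wrs_test(values[9998:10000], values[1:9997],
                method = "uniform", alternative = "greater")
fit
#> Wilcoxon rank-sum test (uniform null approximation)
#>   m = 3, n = 9997, W = 29997, U = 29991
#>   alternative = greater, p = 7.14614e-12
```

`7.15e-12` is a factor 1.2 from the exact `extreme_case_exact_p(3, 10000)`
= `6.00e-12`; the normal back-end reports `1.35e-3` for the same data.

Enrichment on a synthetic universe with 6 spiked sets out of 40
(5 genes each, members shifted by +3):

```r
fx  <- make_fixture(n_genes = 10000, set_sizes = 5, n_sets = 40,
                    spike_fraction = 0.15, effect = 3, seed = 1, dir = NULL)
res <- wrs_enrich(fx$stats, fx$sets)
head(res, 3)
#> # A tibble: 3 × 10
#>   term     name      size     W     U direction p_uniform p_normal   p_used p_adjusted
#> 1 SET:0002 SET:0002     5 49893 49878 up         2.13e-12 0.000115 2.13e-12   8.52e-11
#> 2 SET:0004 SET:0004     5 49869 49854 up         5.96e-12 0.000117 5.96e-12   2.38e-10
#> 3 SET:0006 SET:0006     5 49852 49837 up         1.11e-11 0.000118 1.11e-11   4.43e-10
```

All six spiked sets head the table with Bonferroni-adjusted uniform
p-values below `1e-5`; note the eight-orders-of-magnitude gap between
`p_uniform` and `p_normal` on the same data.  The same run from the shell:

```sh
uniwrs enrich --stats stats.tsv --gmt sets.gmt --out enrichment.tsv
uniwrs pvalue --extreme --m 3 --N 10000 --method uniform --alternative greater
# 7.15e-12
```

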