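# Wilcoxon rank-sum test for one small group against a huge complement, with
# three back-ends for the null distribution of the rank sum W:
#   * uniform  -- Irwin-Hall approximation to the affinely standardized W,
#                 the accurate choice for small m against genome-scale n;
#   * normal   -- the classical continuity-corrected normal approximation;
#   * exact    -- the shift-algorithm permutation distribution (small N only).

#' Midranks of a numeric vector
#'
#' Tied values receive the average of the ranks they span (the midrank
#' convention); the ranks of an `N`-vector always sum to `N(N+1)/2`.
#'
#' @param values numeric vector of finite values (no `NA`/`NaN`; unscored
#'   genes must be filtered out upstream).
#' @return numeric vector of (mid)ranks.
#' @export
midranks <- function(values) {
  if (length(values) == 0L || !is.numeric(values) || anyNA(values) ||
      any(!is.finite(values))) {
    stop("`values` must be a nonempty numeric vector of finite values",
         call. = FALSE)
  }
  rank(values, ties.method = "average")
}

#' Tie correction factor for the rank-sum variance
#'
#' The quantity `TF = sum(d^3 - d) / (N (N - 1))` over the multiplicities
#' `d` of the distinct values in the pooled sample.  It deflates the null
#' variance of the rank sum to `m n (N + 1 - TF) / 12`; `TF = 0` exactly when
#' there are no ties.
#'
#' @param tie_counts integer vector of multiplicities of the distinct pooled
#'   values; must sum to `N`.
#' @param N total pooled sample size (`>= 2`).
#' @return the tie factor, a nonnegative scalar.
#' @export
tie_factor <- function(tie_counts, N) {
  stopifnot(N >= 2, all(tie_counts >= 1))
  if (sum(tie_counts) != N) {
    stop("`tie_counts` must sum to `N`", call. = FALSE)
  }
  sum(tie_counts^3 - tie_counts) / (N * (N - 1))
}

#' Rank decomposition of a two-group sample
#'
#' Pools the two groups, assigns midranks, and returns the pieces every WRS
#' back-end consumes: group sizes, the rank sum `W` of the first group, the
#' Mann-Whitney statistic `U = W - m(m+1)/2`, and the tie multiplicities.
#'
#' @param set_values numeric vector for group X (the gene set).
#' @param complement_values numeric vector for group Y (the complement).
#' @return a list of class `"rank_summary"` with elements `m`, `n`, `N`,
#'   `W`, `U`, `tie_counts`, `tf`.
#' @export
rank_summary <- function(set_values, complement_values) {
  x <- set_values
  y <- complement_values
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  pooled <- c(x, y)
  r <- midranks(pooled)
  m <- length(x)
  n <- length(y)
  N <- m + n
  W <- sum(r[seq_len(m)])
  tie_counts <- as.integer(table(pooled))
  structure(
    list(m = m, n = n, N = N, W = W, U = W - m * (m + 1) / 2,
         tie_counts = tie_counts, tf = tie_factor(tie_counts, N)),
    class = "rank_summary"
  )
}

#' Map the rank sum onto the Irwin-Hall scale
#'
#' The standardized rank sum `(W - c) / d` of a group of `m` converges, as the
#' complement grows, to a sum of `m` independent uniform(0,1) variables.  The
#' affine constants are fixed by matching the first two moments:
#' `d = sqrt(n (N + 1 - TF))` and `c = m (N + 1) / 2 - m d / 2`, so that
#' `W = E[W]` maps to the Irwin-Hall mean `m/2` and `var(W)/d^2 = m/12`.
#' The discrete `W` is widened by the 0.5 continuity correction before the
#' continuous CDF is applied (`+0.5` for the lower tail, `-0.5` upper).
#'
#' @param summary a [rank_summary()] object.
#' @param tf tie factor; defaults to the one recorded in `summary`.
#' @return a list of class `"uniform_standardization"` with elements `tf`,
#'   `var_w`, `d`, `c`, `u_lower`, `u_upper`.
#' @export
uniform_standardize <- function(summary, tf = summary$tf) {
  m <- summary$m; n <- summary$n; N <- summary$N; W <- summary$W
  var_w <- m * n * (N + 1 - tf) / 12
  if (var_w <= 0) {
    stop("degenerate data: all pooled values tied, rank-sum variance is zero",
         call. = FALSE)
  }
  d <- sqrt(n * (N + 1 - tf))
  cc <- m * (N + 1) / 2 - m * d / 2
  structure(
    list(tf = tf, var_w = var_w, d = d, c = cc,
         u_lower = (W - cc + 0.5) / d,
         u_upper = (W - cc - 0.5) / d),
    class = "uniform_standardization"
  )
}

new_wrs_result <- function(summary, alternative, method, p_less, p_greater) {
  p_less <- min(max(p_less, 0), 1)
  p_greater <- min(max(p_greater, 0), 1)
  p <- switch(alternative,
    "two.sided" = min(1, 2 * min(p_less, p_greater)),
    "greater" = p_greater,
    "less" = p_less
  )
  structure(
    list(summary = summary, alternative = alternative, method = method,
         p_one_sided_less = p_less, p_one_sided_greater = p_greater, p = p),
    class = "wrs_test"
  )
}

#' WRS p-value from the uniform (Irwin-Hall) approximation
#'
#' @param summary a [rank_summary()] object.
#' @param tf tie factor (defaults to the one in `summary`).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`;
#'   the two-sided p-value is twice the smaller one-sided one, clamped at 1.
#' @return a `"wrs_test"` object; see [wrs_test()].
#' @export
uniform_p <- function(summary, tf = summary$tf,
                      alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  st <- uniform_standardize(summary, tf)
  m <- summary$m
  p_less <- pirwinhall(st$u_lower, m)
  p_greater <- pirwinhall(st$u_upper, m, lower.tail = FALSE)
  out <- new_wrs_result(summary, alternative, "uniform", p_less, p_greater)
  out$standardization <- st
  out
}

#' WRS p-value from the normal approximation
#'
#' Continuity-corrected normal approximation with null mean `m(N+1)/2` and
#' variance `m n (N + 1 - TF) / 12`, matching the behaviour of standard
#' rank-sum implementations such as `stats::wilcox.test(correct = TRUE)`.
#'
#' @inheritParams uniform_p
#' @return a `"wrs_test"` object.
#' @export
normal_p <- function(summary, tf = summary$tf,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  m <- summary$m; n <- summary$n; N <- summary$N; W <- summary$W
  var_w <- m * n * (N + 1 - tf) / 12
  if (var_w <= 0) {
    stop("degenerate data: all pooled values tied, rank-sum variance is zero",
         call. = FALSE)
  }
  mu <- m * (N + 1) / 2
  sd_w <- sqrt(var_w)
  p_less <- stats::pnorm((W - mu + 0.5) / sd_w)
  p_greater <- stats::pnorm((W - mu - 0.5) / sd_w, lower.tail = FALSE)
  new_wrs_result(summary, alternative, "normal", p_less, p_greater)
}

#' Exact one-sided p-value for the most extreme configuration
#'
#' When all `m` gene-set statistics exceed (or all fall below) every one of
#' the `N - m` complement statistics and there are no ties, exactly one of the
#' `choose(N, m)` equally likely rank assignments is as extreme, so the
#' one-sided permutation p-value is `1 / choose(N, m)`, computed in log space
#' so genome-scale `N` poses no overflow problem.
#'
#' @param m gene set size, `1 <= m < N`.
#' @param N total number of genes.
#' @return the one-sided exact p-value.
#' @examples
#' extreme_case_exact_p(3, 10000)   # ~6.00e-12
#' @export
extreme_case_exact_p <- function(m, N) {
  stopifnot(length(m) == 1L, length(N) == 1L, m == round(m), N == round(N))
  if (m < 1 || m >= N) stop("require 1 <= m < N", call. = FALSE)
  exp(-lchoose(N, m))
}

#' Wilcoxon rank-sum test of a gene set against its complement
#'
#' Facade composing [midranks()], [tie_factor()] and the chosen null
#' back-end.  `method = "uniform"` is the accurate choice for small sets
#' (`m < 30`) against a genome-scale complement; `"normal"` is the classical
#' approximation (adequate for `m >= 30`); `"exact"` computes the full
#' permutation distribution with the shift algorithm and is capped at small
#' totals; `"auto"` picks uniform below 30 set genes and normal otherwise.
#'
#' @param set_values numeric vector of local statistics for the gene set.
#' @param complement_values numeric vector for all other genes.
#' @param method `"uniform"`, `"normal"`, `"exact"` or `"auto"`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#'   `"greater"` means the set's statistics are stochastically larger than the
#'   complement's.
#' @param exact_cap refuse exact computation above this pooled size.
#' @return an object of class `"wrs_test"`: the rank decomposition, the
#'   back-end used, and one- and two-sided p-values.  `tidy()` and `glance()`
#'   methods return tibble summaries.
#' @examples
#' wrs_test(c(9.1, 8.7, 7.9), rnorm(500), method = "uniform")
#' @export
wrs_test <- function(set_values, complement_values,
                     method = c("uniform", "normal", "exact", "auto"),
                     alternative = c("two.sided", "greater", "less"),
                     exact_cap = 200L) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  s <- rank_summary(set_values, complement_values)
  if (method == "auto") method <- if (s$m < 30) "uniform" else "normal"
  switch(method,
    uniform = uniform_p(s, alternative = alternative),
    normal = normal_p(s, alternative = alternative),
    exact = exact_p_shift(set_values, complement_values,
                          alternative = alternative, cap = exact_cap)
  )
}

# Fast scalar path used by the enrichment driver and the simulations, where
# the pooled ranks (hence W, m, n, tf) are already known: returns
# c(p_less, p_greater) for one back-end without rebuilding a rank_summary.
wrs_p_components <- function(W, m, n, tf, method) {
  N <- m + n
  if (method == "uniform") {
    d <- sqrt(n * (N + 1 - tf))
    cc <- m * (N + 1) / 2 - m * d / 2
    c(pirwinhall((W - cc + 0.5) / d, m),
      pirwinhall((W - cc - 0.5) / d, m, lower.tail = FALSE))
  } else {
    mu <- m * (N + 1) / 2
    sd_w <- sqrt(m * n * (N + 1 - tf) / 12)
    c(stats::pnorm((W - mu + 0.5) / sd_w),
      stats::pnorm((W - mu - 0.5) / sd_w, lower.tail = FALSE))
  }
}

two_sided <- function(p_less, p_greater) {
  pmin(1, 2 * pmin(p_less, p_greater))
}

#' @export
print.wrs_test <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Wilcoxon rank-sum test (%s null approximation)\n", x$method))
  cat(sprintf("  m = %d, n = %d, W = %g, U = %g%s\n", s$m, s$n, s$W, s$U,
              if (s$tf > 0) sprintf(", tie factor = %.4g", s$tf) else ""))
  cat(sprintf("  alternative = %s, p = %.6g\n", x$alternative, x$p))
  invisible(x)
}
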