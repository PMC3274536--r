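#' Exact WRS p-value by the shift algorithm
#'
#' Builds the full permutation null distribution of the rank sum over the
#' `choose(N, m)` equally likely assignments of the observed (mid)rank
#' multiset, by dynamic programming over doubled midranks, and reads the tail
#' probability off it.  Exact under ties.  Feasible only for small pooled
#' sizes; production-scale testing should use the uniform or normal
#' approximation, which is why this back-end refuses above `cap`.
#'
#' @inheritParams wrs_test
#' @param cap maximum pooled size `N` (default 200).
#' @return a `"wrs_test"` object; see [wrs_test()].
#' @export
exact_p_shift <- function(set_values, complement_values,
                          alternative = c("two.sided", "greater", "less"),
                          cap = 200L) {
  alternative <- match.arg(alternative)
  s <- rank_summary(set_values, complement_values)
  if (s$N > cap) {
    stop("pooled size N = ", s$N, " exceeds the exact-computation cap (",
         cap, "); use the uniform (m < 30) or normal approximation instead",
         call. = FALSE)
  }
  dist <- exact_rank_sum_distribution(
    midranks(c(set_values, complement_values)), s$m)
  w2 <- as.integer(round(2 * s$W))
  p_greater <- sum(dist$prob[dist$sum2 >= w2])
  p_less <- sum(dist$prob[dist$sum2 <= w2])
  new_wrs_result(s, alternative, "exact", p_less, p_greater)
}

# Full exact null distribution of the rank sum of an m-subset of `ranks`
# (a midrank multiset).  Returns a list with the achievable doubled sums,
# their probabilities, and the subset counts.
exact_rank_sum_distribution <- function(ranks, m) {
  ranks2 <- as.integer(round(2 * ranks))
  if (any(abs(2 * ranks - ranks2) > 1e-9)) {
    stop("midranks must be multiples of 0.5", call. = FALSE)
  }
  counts <- shift_count_subsets(ranks2, as.integer(m))
  sum2 <- seq_along(counts) - 1L
  keep <- counts > 0
  log_total <- lchoose(length(ranks), m)
  list(sum2 = sum2[keep], count = counts[keep],
       prob = exp(log(counts[keep]) - log_total))
}
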