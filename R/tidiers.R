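#' Tidy a WRS test result
#'
#' @param x a `"wrs_test"` object.
#' @param ... unused.
#' @return a one-row tibble with the statistic, the back-end used and the
#'   one- and two-/one-sided p-values, in the style of `broom::tidy.htest`.
#' @export
tidy.wrs_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$summary$W,
    u_statistic = x$summary$U,
    p.value = x$p,
    p.less = x$p_one_sided_less,
    p.greater = x$p_one_sided_greater,
    method = x$method,
    alternative = x$alternative
  )
}

#' One-row summary of a WRS test's design
#'
#' @param x a `"wrs_test"` object.
#' @param ... unused.
#' @return a one-row tibble with group sizes, tie factor and p-value.
#' @export
glance.wrs_test <- function(x, ...) {
  s <- x$summary
  tibble::tibble(m = s$m, n = s$n, N = s$N, W = s$W, U = s$U,
                 tie_factor = s$tf, method = x$method, p.value = x$p)
}

#' Aggregate a simulation to mean rates
#'
#' @param x a `wrs_sim` tibble from [simulate_fpr()] or [simulate_power()].
#' @param ... unused.
#' @return a tibble with the mean rate over rounds and its Monte-Carlo
#'   standard error per simulation cell.
#' @export
tidy.wrs_sim <- function(x, ...) {
  keys <- intersect(c("method", "m", "alpha", "delta"), names(x))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x),
                    dplyr::across(dplyr::all_of(keys))),
    mean_rate = mean(.data$rate),
    mc_se = stats::sd(.data$rate) / sqrt(dplyr::n()),
    rounds = dplyr::n(),
    .groups = "drop"
  )
}
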