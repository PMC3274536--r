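# ggplot2 views of the package's result types.

#' Plot a simulation result
#'
#' Power simulations are drawn as power-versus-effect-size curves (one panel
#' per set size, one colour per approximation); false-positive-rate
#' simulations as calibration bars against the nominal level.
#'
#' @param object a `wrs_sim` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wrs_sim <- function(object, ...) {
  type <- attr(object, "sim_type")
  agg <- tidy.wrs_sim(object)
  if (identical(type, "power")) {
    ggplot2::ggplot(agg, ggplot2::aes(x = .data$delta, y = .data$mean_rate,
                                      colour = .data$method)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 1) +
      ggplot2::facet_wrap(ggplot2::vars(.data$m), labeller = "label_both") +
      ggplot2::labs(x = expression(delta), y = "power",
                    colour = "approximation") +
      ggplot2::theme_bw()
  } else {
    ggplot2::ggplot(agg, ggplot2::aes(x = factor(.data$m),
                                      y = .data$mean_rate,
                                      fill = .data$method)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_hline(ggplot2::aes(yintercept = .data$alpha),
                          linetype = 2) +
      ggplot2::facet_wrap(ggplot2::vars(.data$alpha), scales = "free_y",
                          labeller = "label_both") +
      ggplot2::labs(x = "gene set size m", y = "false positive rate",
                    fill = "approximation") +
      ggplot2::theme_bw()
  }
}

#' Compare the two approximations across gene sets
#'
#' Scatter of -log10 p-values, normal versus uniform approximation, with the
#' identity line and a significance cutoff; the small-set excess below the
#' identity line is the normal approximation's loss of tail accuracy.
#'
#' @param enrichment a tibble from [wrs_enrich()].
#' @param cutoff significance level drawn as guide lines after Bonferroni
#'   correction over the tested sets (default 0.05).
#' @return a ggplot object.
#' @export
plot_approximation_comparison <- function(enrichment, cutoff = 0.05) {
  stopifnot(all(c("p_uniform", "p_normal") %in% names(enrichment)))
  thr <- -log10(cutoff / max(nrow(enrichment), 1L))
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = -log10(.data$p_uniform),
                               y = -log10(.data$p_normal))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_hline(yintercept = thr, colour = "blue", linetype = 2) +
    ggplot2::geom_vline(xintercept = thr, colour = "blue", linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$size)) +
    ggplot2::labs(x = expression(-log[10] ~ p ~ "(uniform)"),
                  y = expression(-log[10] ~ p ~ "(normal)"),
                  colour = "set size") +
    ggplot2::theme_bw()
}
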