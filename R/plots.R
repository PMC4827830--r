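#' Plot a sweep result
#'
#' `autoplot()` dispatches on the sweep's experiment type: false-detection
#' curves for `p_false_sweep` (exact vs approximate, log scale), SNR vs `M`
#' for `m_sweep` (simulation with error bars over the analytic line), the
#' accuracy-robustness trade-off for `theta_sweep`, error-vs-K curves for
#' `lasso_compare`, and the limit ratio for `limits_table`.
#'
#' @param object A tibble of class `olf_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.olf_sweep <- function(object, ...) {
  switch(attr(object, "experiment") %||% "",
         p_false_sweep = plot_p_false_curve(object),
         m_sweep = plot_m_sweep(object),
         theta_sweep = plot_threshold_sweep(object),
         lasso_compare = plot_lasso_comparison(object),
         limits_table = plot_limits(object),
         robustness = ggplot2::ggplot(object,
             ggplot2::aes(x = .data$stuck_on_fraction, y = .data$p_false)) +
           ggplot2::geom_pointrange(ggplot2::aes(
             ymin = .data$p_false - .data$p_false_se,
             ymax = .data$p_false + .data$p_false_se)) +
           ggplot2::labs(x = "stuck-on fraction", y = "false-detection rate"),
         abort("no plot method for this sweep type"))
}

#' @rdname autoplot.olf_sweep
#' @param sweep A sweep tibble of the matching experiment type.
#' @export
plot_p_false_curve <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, dplyr::starts_with("p_false"),
                              names_to = "formula", values_to = "p_false",
                              names_prefix = "p_false_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$p, y = .data$p_false,
                                     linetype = .data$formula)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "connectivity rate p", y = "false-detection rate",
                  linetype = NULL)
}

#' @rdname autoplot.olf_sweep
#' @export
plot_m_sweep <- function(sweep) {
  shown <- dplyr::filter(sweep, is.finite(.data$snr_sim))
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$M)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$snr_analytic)) +
    ggplot2::geom_pointrange(
      data = shown,
      ggplot2::aes(y = .data$snr_sim,
                   ymin = .data$snr_sim - .data$snr_sim_se,
                   ymax = .data$snr_sim + .data$snr_sim_se)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "number of glomeruli M", y = "SNR (optimal p)")
}

#' @rdname autoplot.olf_sweep
#' @export
plot_threshold_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(
    dplyr::select(sweep, "theta_r", "p_false", "miss_rate"),
    c("p_false", "miss_rate"), names_to = "metric", values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$theta_r, y = .data$rate,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "recovery threshold", y = "rate", colour = NULL)
}

#' @rdname autoplot.olf_sweep
#' @export
plot_lasso_comparison <- function(sweep) {
  cols <- intersect(c("ff_error", "lasso_error", "lasso_capped_error"),
                    names(sweep))
  long <- tidyr::pivot_longer(dplyr::select(sweep, "K", dplyr::all_of(cols)),
                              dplyr::all_of(cols),
                              names_to = "decoder", values_to = "l1_error")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$K, y = .data$l1_error,
                                     colour = .data$decoder)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "odor sparsity K", y = "mean l1 reconstruction error",
                  colour = NULL)
}

#' @rdname autoplot.olf_sweep
#' @export
plot_limits <- function(sweep) {
  shown <- dplyr::filter(sweep, is.finite(.data$ratio))
  ggplot2::ggplot(shown, ggplot2::aes(x = .data$f, y = .data$ratio)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = exp(1) * log(2), linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "relative sparsity f = K/N",
                  y = "alpha_SNR / alpha_min")
}

#' Plot a reconstruction as truth vs estimate
#'
#' @param object An `odor_reconstruction`.
#' @param ... Unused.
#' @return A ggplot object marking hits, misses and false positives.
#' @export
autoplot.odor_reconstruction <- function(object, ...) {
  d <- dplyr::filter(tidy(object), .data$outcome != "correct_reject")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$outcome,
                                  colour = .data$outcome)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::labs(x = "odor component", y = NULL)
}
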