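#' Plot link-scale variance shares
#'
#' Dot-and-interval plot of the posterior variance shares of one fitted
#' model, in the style of a variance-partition figure.
#'
#' @param fit A `perf_mcmc` object.
#' @param prob Credible-interval mass.
#' @return A ggplot object.
#' @export
plot_variance_shares <- function(fit, prob = 0.95) {
  vs <- variance_shares(fit, prob)
  ggplot2::ggplot(vs, ggplot2::aes(x = stats::reorder(.data$component, -.data$share),
                                   y = 100 * .data$share)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = 100 * .data$share_lower,
                                          ymax = 100 * .data$share_upper)) +
    ggplot2::labs(x = NULL, y = "share of link-scale variance (%)",
                  title = sprintf("%s model", fit$spec$response)) +
    ggplot2::theme_minimal()
}

#' Plot per-treatment performance predictions
#'
#' Posterior means and credible intervals per host (or per
#' population-by-host cell), with the posterior grand mean as a horizontal
#' reference line.
#'
#' @param fit A `perf_mcmc` object.
#' @param level `"host"` or `"cell"`.
#' @param prob Credible-interval mass.
#' @return A ggplot object.
#' @export
plot_treatment_predictions <- function(fit, level = c("host", "cell"),
                                       prob = 0.95) {
  level <- match.arg(level)
  tp <- treatment_predictions(fit, level, prob = prob)
  grand <- mean(prediction_draws(fit, level))
  p <- ggplot2::ggplot(tp, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = grand, linewidth = 0.3) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::labs(x = NULL, y = tp$metric[1]) +
    ggplot2::theme_minimal()
  if (level == "cell") {
    p <- p + ggplot2::facet_wrap(~ .data$host, scales = "free_x") +
      ggplot2::aes(x = .data$population)
  }
  p + ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn plot_variance_shares `autoplot` method: variance shares of a
#'   fit.
#' @param object A `perf_mcmc` object.
#' @param ... Unused.
#' @export
autoplot.perf_mcmc <- function(object, ...) plot_variance_shares(object)

#' Plot a derived posterior metric
#'
#' @param object A `derived_posterior` (development rate or projected
#'   fitness).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.derived_posterior <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = s$mean[s$group == "overall"],
                        linewidth = 0.3) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::labs(x = NULL, y = object$metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
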