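#' Plot federated learning curves
#'
#' Held-out AUROC and training binary cross-entropy per site versus
#' aggregation round, the standard picture of federated convergence.
#'
#' @param object An `fc_round_log` from [run_federated()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot fc_round_log
autoplot.fc_round_log <- function(object, ...) {
  curves <- learning_curves(object) |>
    pivot_longer(all_of(c("auroc", "bce")),
                 names_to = "metric", values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$round, y = .data$value,
                               colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(auroc = "held-out AUROC", bce = "training BCE"))) +
    ggplot2::labs(x = "aggregation round", y = NULL, colour = "site") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap experiment results
#'
#' Point-range plot of mean AUROC with 95% CI per site; several experiments
#' (strategies/families) can be overlaid with [plot_strategy_comparison()].
#'
#' @param object An `fc_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot fc_experiment
autoplot.fc_experiment <- function(object, ...) {
  plot_strategy_comparison(list(object))
}

#' @rdname autoplot.fc_experiment
#' @param results List of `fc_experiment` objects.
#' @export
plot_strategy_comparison <- function(results) {
  summary <- purrr::list_rbind(lapply(results, function(r) r$summary))
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$site, y = .data$auroc_mean,
                               colour = .data$strategy)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = NULL, y = "AUROC (mean, 95% CI)", colour = "strategy") +
    ggplot2::theme_minimal()
}
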