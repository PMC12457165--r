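#' Violin plot of per-fold metrics for a trait report
#'
#' One violin (with fold points) per metric, the display used to compare
#' cross-validation variability across models.
#'
#' @param object A `trait_report` from [evaluate_trait()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trait_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40") +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(title = paste0(object$trait, " (", object$kind, ")"),
                  subtitle = sprintf("pseudo-h2 = %.3f", object$pseudo_h2),
                  x = NULL, y = "per-fold value") +
    ggplot2::theme_minimal()
}

#' Compare per-fold metrics across several trait reports
#'
#' @param reports Named list of `trait_report`s (names label the models).
#' @param metric Which metric column to plot (must be present in each
#'   report's per-fold table).
#' @param null_value Reference line for a no-skill model (0.5 for AUROC,
#'   0 for correlations; default 0).
#' @return A ggplot object.
#' @export
plot_report_comparison <- function(reports, metric, null_value = 0) {
  d <- dplyr::bind_rows(lapply(reports, function(r) r$per_fold),
                        .id = "model")
  if (!metric %in% names(d)) stop("metric not present: ", metric)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data[[metric]])) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40") +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2) +
    ggplot2::geom_hline(yintercept = null_value, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
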