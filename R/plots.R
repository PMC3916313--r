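#' Plot case-control differences in cell proportions
#'
#' Point estimates with 95% confidence bars for the case-minus-control
#' difference in each leukocyte fraction.
#'
#' @param object A `proportion_contrast` tibble from
#'   [compare_proportions()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot proportion_contrast
#' @export
autoplot.proportion_contrast <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$cell_type <- factor(df$cell_type, levels = CELL_TYPES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::labs(x = NULL, y = "difference in fraction (case - control)") +
    ggplot2::theme_minimal()
}

#' Volcano plot of an EWAS result
#'
#' Effect (M-value difference, case minus control) against
#' `-log10(q value)`, with reference lines at q = 0.05 and q = 0.10.
#'
#' @param object An `ewas_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ewas_result
#' @export
autoplot.ewas_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = -log10(.data$q_value))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(c(0.05, 0.10)),
                        linetype = "dashed", colour = c("red", "blue")) +
    ggplot2::labs(x = "M-value difference (case - control)",
                  y = expression(-log[10](q))) +
    ggplot2::theme_minimal()
}

#' Histogram of association p-values
#'
#' Diagnostic for EWAS calibration: under the global null the histogram
#' is flat at the dashed reference line.
#'
#' @param result A tibble with a `p_value` column.
#' @param bins Number of histogram bins.
#' @return A ggplot.
#' @export
plot_pvalue_histogram <- function(result, bins = 20) {
  df <- tibble::as_tibble(result)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, boundary = 0, fill = "grey70",
                            colour = "white") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "p-value", y = "density") +
    ggplot2::theme_minimal()
}
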