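# Optional ggplot2 figures; the CSVs written by the run_* entry points are
# the canonical outputs.

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the 'ggplot2' package")
  }
}

.save_plot <- function(p, path, width = 7, height = 5) {
  .need_ggplot()
  grDevices::pdf(path, width = width, height = height)
  print(p)
  grDevices::dev.off()
  invisible(path)
}

#' Tornado diagram of the one-way sensitivity analysis
#'
#' @param results A `dsa_results` data frame from [one_way_dsa()].
#' @return A ggplot object.
#' @export
plot_tornado <- function(results) {
  .need_ggplot()
  d <- results
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  d$lo <- pmin(d$icer_at_low, d$icer_at_high)
  d$hi <- pmax(d$icer_at_low, d$icer_at_high)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$lo, xend = .data$hi,
                   y = .data$parameter, yend = .data$parameter),
      linewidth = 5, colour = "steelblue") +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL,
                  title = "One-way sensitivity of the ICER") +
    ggplot2::theme_minimal()
}

#' Incremental cost-effectiveness scatterplot of PSA draws
#'
#' @param psa A `psa_draws` object.
#' @param wtp Willingness-to-pay threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_psa_scatter <- function(psa, wtp = 50000) {
  .need_ggplot()
  d <- psa$draws
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_qaly,
                                  y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_abline(intercept = 0, slope = wtp, linetype = "dashed") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = "PSA scatter (dashed line: WTP threshold)") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param cc Data frame from [ceac()].
#' @param wtp Threshold marked with a vertical line.
#' @return A ggplot object.
#' @export
plot_ceac <- function(cc, wtp = 50000) {
  .need_ggplot()
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$wtp,
                                   y = .data$fraction_accepted)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = wtp, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
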