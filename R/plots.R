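# ggplot2 views of the result tables. Each takes the tidy table a stage
# returns, so plots can be rebuilt from written TSVs.

#' Heatmap of within-patient cross-platform correlations
#'
#' @param correlations Output of [platform_correlation_matrix()].
#' @return A ggplot object (tiles: patient x platform pair, fill = rho).
#' @export
plot_correlation_heatmap <- function(correlations) {
  d <- mutate(correlations,
              pair = paste(.data$platform_1, .data$platform_2, sep = " vs "))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pair, y = .data$patient,
                                  fill = .data$rho)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       size = 2.8) +
    ggplot2::scale_fill_gradient(low = "#c6dbef", high = "#08519c",
                                 limits = c(min(d$rho, 0.6), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho",
                  title = "Within-patient expression concordance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Outlier z-scores by platform
#'
#' Shows, for each called outlier (gene, sample), its cohort z-score per
#' platform — the cross-platform recovery view of actionable-gene
#' overexpression.
#'
#' @param calls Output of [call_outliers()]; only `is_outlier` rows are
#'   shown.
#' @return A ggplot object.
#' @export
plot_outlier_z <- function(calls) {
  d <- filter(calls, .data$is_outlier)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$z,
                                  colour = .data$platform)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~gene, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "cohort z-score",
                  title = "Expression outliers across platforms") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Fusion detection matrix tile plot
#'
#' @param detection The `matrix` element of [build_detection_matrix()].
#' @return A ggplot object (fusion x platform tiles coloured by status).
#' @export
plot_detection_matrix <- function(detection) {
  d <- mutate(detection, label = paste(.data$patient, .data$fusion))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$platform, y = .data$label,
                                  fill = .data$status)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(detected = "#31a354",
                                          not_detected = "#de2d26",
                                          no_sample = "grey85")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Fusion detection across platforms") +
    ggplot2::theme_minimal()
}

#' Pooled expression density with marked peaks
#'
#' @param matrix Expression tibble.
#' @param peaks Optional precomputed [expression_peaks()] table.
#' @return A ggplot object of the pooled log2(FPKM + 1) density.
#' @export
plot_expression_density <- function(matrix, peaks = NULL) {
  v <- as.vector(expr_to_matrix(matrix))
  d <- tibble(log2_fpkm = log2(v + 1))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fpkm)) +
    ggplot2::geom_density(fill = "#9ecae1", alpha = 0.6) +
    ggplot2::labs(x = "log2(FPKM + 1)", y = "density",
                  title = "Pooled expression density") +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_vline(data = peaks,
                                 ggplot2::aes(xintercept = .data$peak_log2),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
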