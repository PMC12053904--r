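#' Quick-look plots for pipeline outputs
#'
#' Thin ggplot2 wrappers over the tabular results: diversity metrics over
#' time, the PC1 trajectory, nearest-neighbor dissimilarity, panel totals,
#' and the monthly residual panels (the tabular analogue of a ridgeline
#' figure). All return a `ggplot` object for further styling.
#'
#' @param profiles Output of [diversity_series()].
#' @name plots
NULL

#' @rdname plots
#' @export
plot_diversity_series <- function(profiles) {
  long <- tidyr::pivot_longer(profiles, c("shannon", "richness", "pielou"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Alpha diversity over time")
}

#' @rdname plots
#' @param pca A [pca_ordination()] result.
#' @param metadata Sample metadata (for dates).
#' @export
plot_pc1 <- function(pca, metadata) {
  sc <- tidy(pca, "scores") %>%
    left_join(sample_metadata(metadata)[, c("sample_id", "date")],
              by = "sample_id")
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$date, y = .data$PC1)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = NULL, title = "PC1 of community structure over time")
}

#' @rdname plots
#' @param nn Output of [nn_dissimilarity()].
#' @export
plot_nn_dissimilarity <- function(nn) {
  ggplot2::ggplot(nn, ggplot2::aes(x = .data$date, y = .data$nn_dist)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = NULL, y = "Euclidean distance to previous sample",
                  title = "Nearest-neighbor dissimilarity")
}

#' @rdname plots
#' @param totals Output of [panel_total()].
#' @export
plot_panel_totals <- function(totals, metadata) {
  df <- left_join(totals, sample_metadata(metadata)[, c("sample_id", "date")],
                  by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = 100 * .data$total)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = NULL, y = "summed relative abundance (%)",
                  title = "Responder panel total")
}

#' @rdname plots
#' @param panel Output of [monthly_anomaly_panel()].
#' @export
plot_monthly_panel <- function(panel) {
  base <- filter(panel, .data$period == "baseline")
  post <- filter(panel, .data$period == "post")
  ggplot2::ggplot(base, ggplot2::aes(x = .data$residual)) +
    ggplot2::geom_density(fill = "grey85", color = "grey40") +
    ggplot2::geom_point(data = post,
                        ggplot2::aes(y = 0, color = .data$flag), shape = 8) +
    ggplot2::facet_wrap(~month, scales = "free") +
    ggplot2::scale_color_manual(
      values = c(low = "#2166ac", normal = "grey30", high = "#b2182b")) +
    ggplot2::labs(x = "baseline residual (z units)", y = "density",
                  title = "Monthly residual distributions with post-period samples")
}
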