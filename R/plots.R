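# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_line
#'   geom_smooth facet_wrap scale_x_log10 scale_y_log10 labs theme_minimal
#'   scale_fill_gradient
#' @export
ggplot2::autoplot

#' @export
autoplot.quantweb_network <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$parasitoid, y = .data$host, fill = .data$weight)) +
    geom_tile() +
    scale_fill_gradient(low = "grey90", high = "firebrick") +
    labs(title = sprintf("%s (m = %s)", object$network_id,
                         format(matrix_size(object))),
         x = "parasitoid", y = "host", fill = "events") +
    theme_minimal()
}

#' @export
autoplot.quantweb_rarefaction <- function(object, ...) {
  ggplot(object, aes(x = .data$size, y = .data$mean,
                     group = .data$network_id)) +
    geom_line(alpha = 0.6) +
    scale_x_log10() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "subsampled matrix size (events)",
         y = "mean metric across replicates") +
    theme_minimal()
}

#' Metric-versus-size scatter for a metric table
#'
#' One panel per metric, log-log axes (linear y for H2' and
#' modularity), coloured by study — the visual counterpart of the
#' metric-on-size regressions.
#'
#' @param metrics Output of [network_metrics()].
#' @return A ggplot object.
#' @export
plot_metric_size <- function(metrics) {
  long <- tidyr::pivot_longer(metrics,
                              cols = dplyr::any_of(metric_names),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$m, y = .data$value, colour = .data$study_id)) +
    geom_point(alpha = 0.7, show.legend = FALSE) +
    scale_x_log10() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "matrix size m (events, log scale)", y = "metric value") +
    theme_minimal()
}
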