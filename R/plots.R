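#' Plot junction-positive nuclei percentages
#'
#' Bar chart of the percentage of nuclei positive for each junction, by
#' condition, faceted over clusters.
#'
#' @param object a junction summary from [per_cluster_summary()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.junction_summary <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$junction,
                                   y = .data$percent_positive,
                                   fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "junction", y = "% positive nuclei",
                  fill = "condition") +
    ggplot2::theme_minimal()
}

#' Plot per-sample cell-type composition
#'
#' Stacked bars of each sample's cell-type percentages, grouped by
#' condition.
#'
#' @param object a `frequency_table` from [build_frequency_table()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.frequency_table <- function(object, ...) {
  long <- as_tibble(object) |>
    pivot_longer(-c("sample", "condition"), names_to = "cell_type",
                 values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$percent,
                                     fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(~condition, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "% of nuclei", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-nucleus QC metric distributions
#'
#' Histograms of genes detected and total UMI per nucleus, with an optional
#' threshold line.
#'
#' @param report a `qc_report` from [qc_metrics()].
#' @param threshold optional vertical line (e.g. 200).
#' @return a ggplot object.
#' @export
plot_qc <- function(report, threshold = NULL) {
  long <- report$per_barcode |>
    pivot_longer(c("genes_detected", "total_umi"),
                 names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "nuclei") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
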