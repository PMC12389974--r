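# ggplot2 visualizations for the two diagnostic figures of the workflow:
# the WCSS elbow curve and the PCA cluster/outlier map.

#' Elbow (WCSS) plot
#'
#' Within-cluster sum of squares against the number of clusters, with the
#' selected elbow marked.
#'
#' @param x An `elbow_result` (from [elbow_select_k()]) or a
#'   `target_prioritization`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_elbow <- function(x, ...) {
  elbow <- if (inherits(x, "target_prioritization")) x$elbow else x
  stopifnot(inherits(elbow, "elbow_result"))
  ggplot2::ggplot(elbow$wcss, ggplot2::aes(x = .data$k, y = .data$wcss)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(
      xintercept = elbow$chosen_k,
      linetype = "dashed", color = "firebrick"
    ) +
    ggplot2::scale_x_continuous(breaks = elbow$wcss$k) +
    ggplot2::labs(
      x = "Number of clusters k",
      y = "Within-cluster sum of squares",
      title = sprintf("Elbow selection: k = %d%s", elbow$chosen_k,
        if (elbow$weak_elbow) " (weak elbow)" else ""
      )
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot elbow_result
#' @export
autoplot.elbow_result <- function(object, ...) plot_elbow(object, ...)

#' PCA cluster map of a prioritization
#'
#' First two principal components of the standardized feature matrix,
#' colored by K-means cluster; Isolation-Forest outliers are circled and
#' core genes labelled.
#'
#' @param object A `target_prioritization`.
#' @param label_core Label core genes? Default TRUE.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot target_prioritization
#' @export
autoplot.target_prioritization <- function(object, label_core = TRUE, ...) {
  tbl <- object$table
  ve <- object$pca$var_explained
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point(ggplot2::aes(color = factor(.data$cluster)), size = 2) +
    ggplot2::geom_point(
      data = tbl[tbl$is_outlier, , drop = FALSE],
      shape = 21, size = 4, stroke = 1, color = "red", fill = NA
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
      color = "Cluster",
      title = "PCA projection: clusters and anomaly-flagged genes"
    ) +
    ggplot2::theme_minimal()
  if (label_core && any(tbl$is_core)) {
    p <- p + ggplot2::geom_text(
      data = tbl[tbl$is_core, , drop = FALSE],
      ggplot2::aes(label = .data$gene),
      vjust = -1.1, size = 3
    )
  }
  p
}

#' @rdname autoplot.target_prioritization
#' @param x A `target_prioritization`.
#' @param y Unused.
#' @export
plot.target_prioritization <- function(x, y, ...) print(autoplot.target_prioritization(x, ...))

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
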