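# ggplot2 layer: one plot function per result type.

#' Plot a PCA result
#'
#' Scatter of observation scores on two components.  For gene-space PCA
#' results the sample biplot arrows are overlaid; for sample PCA the
#' points can be coloured by an experimental factor.
#'
#' @param object A `pca_result`.
#' @param x,y Component indices for the axes (defaults 1 and 2).
#' @param colour_by Optional vector (one value per observation) used for
#'   the point colour, e.g. a metadata factor.
#' @param label Label points with their observation IDs (default `TRUE`
#'   for sample PCA, `FALSE` otherwise).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, x = 1, y = 2, colour_by = NULL,
                                label = object$kind == "samples", ...) {
  ve <- object$variance_explained
  df <- tibble::tibble(
    id = object$observation_ids,
    sx = object$scores[, x],
    sy = object$scores[, y]
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$sx, .data$sy))
  if (is.null(colour_by)) {
    p <- p + ggplot2::geom_point(size = if (object$kind == "samples") 3 else 0.8,
                                 alpha = if (object$kind == "samples") 1 else 0.6)
  } else {
    df$colour_by <- colour_by
    p <- p + ggplot2::geom_point(
      data = df, size = if (object$kind == "samples") 3 else 0.8,
      ggplot2::aes(colour = .data$colour_by)) +
      ggplot2::labs(colour = NULL)
  }
  if (isTRUE(label)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$id),
                                vjust = -0.8, size = 3)
  }
  if (!is.null(object$arrows)) {
    ar <- tibble::tibble(id = rownames(object$arrows),
                         ax = object$arrows[, x], ay = object$arrows[, y])
    sc_f <- max(abs(c(df$sx, df$sy))) / max(abs(c(ar$ax, ar$ay, 1e-12)))
    p <- p +
      ggplot2::geom_segment(data = ar, colour = "firebrick",
                            ggplot2::aes(x = 0, y = 0,
                                         xend = .data$ax * sc_f,
                                         yend = .data$ay * sc_f)) +
      ggplot2::geom_text(data = ar, colour = "firebrick", size = 3,
                         ggplot2::aes(x = .data$ax * sc_f,
                                      y = .data$ay * sc_f,
                                      label = .data$id))
  }
  p + ggplot2::labs(
    x = sprintf("PC%d (%.1f%%)", x, 100 * ve[x]),
    y = sprintf("PC%d (%.1f%%)", y, 100 * ve[y]),
    title = sprintf("PCA (%s)", object$kind)) +
    ggplot2::theme_bw()
}

#' Scree plot
#'
#' @param pca A `pca_result`.
#' @return A ggplot object: variance explained per component (bars) with
#'   the cumulative fraction (line).
#' @export
plot_scree <- function(pca) {
  plot_scree_df(scree(pca), sprintf("Scree (%s PCA)", pca$kind))
}

#' Profile plot of a gene subset
#'
#' One line per gene across samples, typically of row-centered transformed
#' values from [profile_data()].
#'
#' @param profiles Tibble from [profile_data()].
#' @return A ggplot object.
#' @export
plot_profile <- function(profiles) {
  long <- tidyr::pivot_longer(profiles, -"gene_id",
                              names_to = "sample_id", values_to = "value")
  long$sample_id <- factor(long$sample_id,
                           levels = setdiff(names(profiles), "gene_id"))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$value,
                                     group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "centered transformed value",
                  title = sprintf("Profiles of %d genes", nrow(profiles))) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Boxplot (or violin) of one gene across groups
#'
#' Distribution of a gene's transformed values per sample group,
#' superimposed with jittered individual points.
#'
#' @param summary A `gene_summary` from [gene_finder()].
#' @param violin Draw violins instead of boxplots (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_gene <- function(summary, violin = FALSE) {
  stopifnot(inherits(summary, "gene_summary"))
  pts <- summary$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$group, .data$value,
                                         fill = .data$group))
  p <- if (violin) p + ggplot2::geom_violin(alpha = 0.6)
  else p + ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA)
  p + ggplot2::geom_jitter(width = 0.15, height = 0, size = 2) +
    ggplot2::labs(x = paste(summary$group_by, collapse = " x "),
                  y = "transformed value", title = summary$gene_id) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_bw()
}

#' Heatmap of sample distances or correlations
#'
#' Tile heatmap with samples in the dendrogram order of the clustering
#' (for `sample_dist` objects) or in input order (plain matrices).
#'
#' @param x A `sample_dist` from [sample_distances()] or a symmetric
#'   matrix such as [sample_correlation()] output.
#' @return A ggplot object.
#' @export
plot_sample_heatmap <- function(x) {
  if (inherits(x, "sample_dist")) {
    m <- x$values
    ord <- x$dendrogram_order
    lab <- "distance"
  } else {
    m <- x
    ord <- colnames(m)
    lab <- "value"
  }
  df <- tibble::as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE))
  names(df) <- c("row", "col", "value")
  df$row <- factor(df$row, levels = ord)
  df$col <- factor(df$col, levels = rev(ord))
  ggplot2::ggplot(df, ggplot2::aes(.data$row, .data$col,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
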