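## Static figure builders mirroring the study's displays. Every function
## returns a ggplot object and never mutates its inputs; rendering is
## deterministic given identical inputs.

#' Spatial map of cell classes
#'
#' @param cells a [cell_matrix()] with centroids.
#' @param labels class per cell (defaults to `cells$labels`).
#' @return a ggplot object (empty axes when no cells).
#' @export
plot_spatial_classes <- function(cells, labels = cells$labels) {
  df <- if (nrow(cells$counts) == 0) {
    data.frame(row = numeric(0), col = numeric(0), class = character(0))
  } else {
    data.frame(row = cells$centroids[, 1], col = cells$centroids[, 2],
               class = if (is.null(labels)) "cell" else as.character(labels))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "bin column", y = "bin row", colour = "class") +
    ggplot2::theme_minimal()
}

#' Ranked PC-loading plot with highlighted markers
#'
#' Genes ordered by their loading on one component; member genes of the
#' chosen marker set are highlighted, mirroring the ranked-contribution
#' display used for the cSCC panel on PC1.
#'
#' @param loadings named loading vector for one PC.
#' @param markers character vector of genes to highlight.
#' @param label_top label the top n marker genes (default 8).
#' @return a ggplot object.
#' @export
plot_loading_ranks <- function(loadings, markers, label_top = 8) {
  ord <- order(loadings, decreasing = TRUE)
  df <- data.frame(rank = seq_along(loadings),
                   loading = loadings[ord],
                   gene = names(loadings)[ord])
  df$marker <- df$gene %in% markers
  lab <- utils::head(df[df$marker, ], label_top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$loading)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$marker), size = 0.7) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$gene),
                       vjust = -0.6, size = 2.8, colour = "red3") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "red3")) +
    ggplot2::labs(x = "gene rank", y = "loading") +
    ggplot2::theme_classic()
}

#' Fraction of cells co-expressing two genes, per group
#'
#' Underlying quantity of the two-colour co-expression display: the
#' fraction of cells with raw counts above zero for both genes, within each
#' group of cells.
#'
#' @param cells a [cell_matrix()].
#' @param gene_a,gene_b gene ids.
#' @param groups grouping vector per cell (e.g. region class).
#' @return named numeric vector of double-positive fractions per group.
#' @export
coexpression_fraction <- function(cells, gene_a, gene_b, groups) {
  for (g in c(gene_a, gene_b))
    if (!g %in% colnames(cells$counts))
      stop("gene-not-found error: ", g)
  dp <- as.numeric(cells$counts[, gene_a]) > 0 &
    as.numeric(cells$counts[, gene_b]) > 0
  tapply(dp, as.character(groups), mean)
}

#' Two-colour spatial co-expression map
#'
#' Each cell is coloured by a blend of two gene intensities (gene A in red,
#' gene B in green, overlap in yellow), on normalized 0-1 scales.
#'
#' @param cells a [cell_matrix()] with centroids.
#' @param gene_a,gene_b gene ids.
#' @return a ggplot object.
#' @export
plot_coexpression <- function(cells, gene_a, gene_b) {
  for (g in c(gene_a, gene_b))
    if (!g %in% colnames(cells$counts))
      stop("gene-not-found error: ", g)
  a <- as.numeric(cells$counts[, gene_a])
  b <- as.numeric(cells$counts[, gene_b])
  sc <- function(v) if (max(v) > 0) v / max(v) else v
  df <- data.frame(row = cells$centroids[, 1], col = cells$centroids[, 2],
                   colour = grDevices::rgb(sc(a), sc(b), 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_point(colour = df$colour, size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "bin column", y = "bin row",
                  title = paste0(gene_a, " (red) / ", gene_b, " (green)")) +
    ggplot2::theme_minimal()
}

#' Violin plot of per-cell values by class
#'
#' @param values numeric vector per cell (expression or activity score).
#' @param labels class per cell.
#' @param ylab axis label.
#' @return a ggplot object.
#' @export
plot_violin_by_class <- function(values, labels, ylab = "value") {
  df <- data.frame(value = values, class = as.character(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$class)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_classic() +
    ggplot2::theme(legend.position = "none")
}

#' Heatmap of regulon specificity or metaprogram activity
#'
#' @param mat numeric matrix (e.g. regulon x class RSS, or class-mean
#'   metaprogram activity).
#' @param value_name legend title.
#' @return a ggplot tile heatmap.
#' @export
plot_score_heatmap <- function(mat, value_name = "score") {
  df <- expand.grid(row = rownames(mat) %||% seq_len(nrow(mat)),
                    col = colnames(mat) %||% seq_len(ncol(mat)),
                    stringsAsFactors = FALSE)
  df$value <- as.vector(mat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = value_name) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Ellipse overlay on 2-D scores
#'
#' @param scores n x 2 score matrix.
#' @param labels class per cell.
#' @param ellipses named list of [fit_t_ellipse()] fits per class.
#' @return a ggplot object.
#' @export
plot_scores_with_ellipses <- function(scores, labels, ellipses = NULL) {
  df <- data.frame(PC1 = scores[, 1], PC2 = scores[, 2],
                   class = as.character(labels))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                        colour = .data$class)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::theme_classic()
  if (!is.null(ellipses)) {
    for (cl in names(ellipses)) {
      b <- ellipse_boundary(ellipses[[cl]])
      bd <- data.frame(PC1 = b[, 1], PC2 = b[, 2], class = cl)
      p <- p + ggplot2::geom_path(data = bd, linewidth = 0.6)
    }
  }
  p
}
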