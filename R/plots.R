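#' Violin plot of per-gene expression by subset
#'
#' Visual companion of the modality screen: zero-inflated, bimodal and
#' shifted genes are immediately visible as multi-bellied violins.
#' Requires ggplot2.
#'
#' @param expr cells x genes Log2Ex matrix.
#' @param meta cell metadata.
#' @param genes genes to show (default: first 12).
#' @return a ggplot object.
#' @export
plot_expression_violin <- function(expr, meta,
                                   genes = utils::head(colnames(expr), 12L)) {
  .assert(requireNamespace("ggplot2", quietly = TRUE), "ggplot2 not available")
  expr <- as.matrix(expr)
  sub <- meta$subset[match(rownames(expr), meta$cell_id)]
  df <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene = g, subset = sub, log2ex = expr[, g])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subset, y = .data$log2ex,
                                   fill = .data$subset)) +
    ggplot2::geom_violin(scale = "width", adjust = 0.8) +
    ggplot2::facet_wrap(~gene) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "Log2Ex")
}

#' PCA score plot with optional subgroup highlighting
#'
#' @param pca [run_pca()] result.
#' @param meta cell metadata.
#' @param highlight optional cell ids drawn with filled symbols (e.g. a
#'   selected subgroup).
#' @param components which two components to draw.
#' @return a ggplot object.
#' @export
plot_pca_scores <- function(pca, meta, highlight = NULL,
                            components = c(1L, 2L)) {
  .assert(requireNamespace("ggplot2", quietly = TRUE), "ggplot2 not available")
  sc <- pca$scores[, components, drop = FALSE]
  df <- data.frame(cell_id = rownames(sc), x = sc[, 1L], y = sc[, 2L])
  df$subset <- meta$subset[match(df$cell_id, meta$cell_id)]
  df$highlight <- df$cell_id %in% (highlight %||% character(0))
  vf <- round(100 * pca$variance_fraction[components], 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$subset,
                                   alpha = .data$highlight)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.4, `TRUE` = 1),
                                guide = "none") +
    ggplot2::theme_bw() +
    ggplot2::labs(x = sprintf("PC%d (%.1f%%)", components[1L], vf[1L]),
                  y = sprintf("PC%d (%.1f%%)", components[2L], vf[2L]))
}
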