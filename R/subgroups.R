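#' Subgroup-discovery configuration
#'
#' Knobs of the deterministic replacement for eyeballing a PCA plot: cells
#' of one subset are 2-partitioned in the leading principal-component
#' dimensions; the minority cluster is accepted as a subgroup only when it
#' is neither trivially small nor a near-half split, and the partition is
#' well separated.
#'
#' @param n_components_for_selection number of leading PCs used (default 2,
#'   matching a 2-D score plot).
#' @param min_subgroup_size smallest acceptable subgroup (cells).
#' @param max_subgroup_fraction largest acceptable subgroup as a fraction of
#'   the subset (must stay below 0.5 so "minority" is meaningful).
#' @param separation_threshold minimum mean silhouette width of the
#'   2-partition, in `[-1, 1]`.
#' @param alpha p-value threshold of the subgroup DE rule.
#' @param min_abs_log2fc fold-change threshold (log2 units) of the DE rule.
#' @return list of class `subgroup_config`.
#' @export
subgroup_config <- function(n_components_for_selection = 2L,
                            min_subgroup_size = 5L,
                            max_subgroup_fraction = 0.4,
                            separation_threshold = 0.45,
                            alpha = 0.05,
                            min_abs_log2fc = 1) {
  .assert(max_subgroup_fraction > 0 && max_subgroup_fraction < 0.5,
          "max_subgroup_fraction must be in (0, 0.5)")
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  structure(list(n_components_for_selection = as.integer(n_components_for_selection),
                 min_subgroup_size = as.integer(min_subgroup_size),
                 max_subgroup_fraction = max_subgroup_fraction,
                 separation_threshold = separation_threshold,
                 alpha = alpha, min_abs_log2fc = min_abs_log2fc),
            class = "subgroup_config")
}

#' Principal component analysis of a Log2Ex matrix
#'
#' Genes are centred (scaling optional, off by default so abundant genes
#' keep their weight, as is conventional for Log2Ex panels). Component signs
#' are fixed deterministically by making the largest-magnitude loading of
#' each component positive.
#'
#' @param expr cells x genes Log2Ex matrix (>= 2 cells, >= 2 genes).
#' @param scale. scale genes to unit variance?
#' @return list of class `scq_pca` with `scores` (cells x components),
#'   `loadings` (genes x components) and `variance_fraction`.
#' @export
run_pca <- function(expr, scale. = FALSE) {
  expr <- as.matrix(expr)
  .assert(nrow(expr) >= 2L && ncol(expr) >= 2L, "need >= 2 cells and genes")
  sds <- apply(expr, 2L, stats::sd)
  .assert(any(sds > 0), "constant matrix: no principal components")
  if (scale.) expr <- expr[, sds > 0, drop = FALSE]
  p <- stats::prcomp(expr, center = TRUE, scale. = scale.)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  structure(list(scores = sweep(p$x, 2L, flip, `*`),
                 loadings = sweep(p$rotation, 2L, flip, `*`),
                 variance_fraction = p$sdev^2 / sum(p$sdev^2)),
            class = "scq_pca")
}

#' Hierarchical clustering orders for a heatmap
#'
#' Agglomerative clustering (Euclidean distance, complete linkage by
#' default) of both cells and genes. Rows and columns are sorted by
#' identifier before clustering so the result is invariant to input order.
#'
#' @param expr cells x genes Log2Ex matrix.
#' @param method linkage passed to [stats::hclust()].
#' @return list with `cell_hclust`, `gene_hclust`, `cell_order`,
#'   `gene_order` (identifier vectors in leaf order).
#' @export
cluster_heatmap_order <- function(expr, method = "complete") {
  expr <- as.matrix(expr)
  expr <- expr[order(rownames(expr)), order(colnames(expr)), drop = FALSE]
  hc_cells <- stats::hclust(stats::dist(expr), method = method)
  hc_genes <- stats::hclust(stats::dist(t(expr)), method = method)
  list(cell_hclust = hc_cells, gene_hclust = hc_genes,
       cell_order = rownames(expr)[hc_cells$order],
       gene_order = colnames(expr)[hc_genes$order])
}

#' Select a candidate minority subgroup within one subset
#'
#' The subset's cells are split in two by k-means in the leading PC
#' dimensions, seeded deterministically with the farthest pair of cells
#' (ties broken by identifier), so the partition does not depend on input
#' order or RNG state. The minority cluster is returned only when its size
#' lies in `[min_subgroup_size, max_subgroup_fraction * n]` and the mean
#' silhouette width of the partition reaches `separation_threshold`;
#' otherwise `NULL` ("no subgroup found").
#'
#' @param pca [run_pca()] result on all cells.
#' @param subset_cells identifiers of the subset's cells (must be at least
#'   `2 * min_subgroup_size`).
#' @param cfg [subgroup_config()]
#' @return `NULL`, or a list with `members`, `separation` and `sizes`.
#' @export
select_subgroup <- function(pca, subset_cells, cfg = subgroup_config()) {
  subset_cells <- sort(as.character(subset_cells))
  .assert(all(subset_cells %in% rownames(pca$scores)),
          "subset cells missing from PCA scores")
  n <- length(subset_cells)
  .assert(n >= 2L * cfg$min_subgroup_size,
          "too few cells (", n, ") for subgroup selection")
  d <- min(cfg$n_components_for_selection, ncol(pca$scores))
  sc <- pca$scores[subset_cells, seq_len(d), drop = FALSE]
  dm <- as.matrix(stats::dist(sc))
  far <- which(dm == max(dm), arr.ind = TRUE)
  far <- far[order(rownames(dm)[far[, 1L]], rownames(dm)[far[, 2L]]), ,
             drop = FALSE][1L, ]
  if (max(dm) == 0) return(NULL)   # all cells identical in PC space
  km <- stats::kmeans(sc, centers = sc[c(far[1L], far[2L]), , drop = FALSE],
                      iter.max = 100L, algorithm = "Lloyd")
  sizes <- km$size
  minority <- which.min(sizes)
  sil <- cluster::silhouette(km$cluster, stats::dist(sc))
  sep <- mean(sil[, "sil_width"])
  members <- subset_cells[km$cluster == minority]
  ok <- length(members) >= cfg$min_subgroup_size &&
    length(members) <= cfg$max_subgroup_fraction * n &&
    sep >= cfg$separation_threshold
  if (!ok) return(NULL)
  list(members = members, separation = sep, sizes = sort(sizes))
}

#' Differential expression between a subgroup and the rest of its subset
#'
#' Per gene, a two-sided two-sample Student t-test of subgroup members
#' against the remaining cells of the subset, with
#' `log2fc = mean(members) - mean(rest)` (Log2Ex is already log2-scale).
#' A gene is reported only when `p < alpha` and
#' `|log2fc| >= min_abs_log2fc`; both thresholds sit in `cfg`.
#'
#' @param expr cells x genes Log2Ex matrix.
#' @param members,rest identifier vectors (both >= 2 cells).
#' @param cfg [subgroup_config()]
#' @return data.frame with columns `gene`, `log2fc`, `p`, `direction`
#'   (`"up"`/`"down"`), possibly empty.
#' @export
subgroup_de <- function(expr, members, rest, cfg = subgroup_config()) {
  expr <- as.matrix(expr)
  .assert(length(members) >= 2L && length(rest) >= 2L,
          "both groups need >= 2 cells")
  .assert(all(c(members, rest) %in% rownames(expr)), "unknown cell ids")
  rows <- lapply(colnames(expr), function(g) {
    r <- .safe_t(expr[members, g], expr[rest, g])
    if (r$p < cfg$alpha && abs(r$log2fc) >= cfg$min_abs_log2fc)
      data.frame(gene = g, log2fc = r$log2fc, p = r$p,
                 direction = if (r$log2fc > 0) "up" else "down")
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), log2fc = numeric(0),
                      p = numeric(0), direction = character(0))
  rownames(out) <- NULL
  out
}

#' Find a subgroup in every subset
#'
#' Per subset: PCA of that subset's cells alone, [select_subgroup()] in its
#' leading components, then [subgroup_de()] against the rest of the subset.
#' The PCA is recomputed within each subset because the leading components
#' of a joint PCA span the between-subset axes, where within-subset
#' substructure is invisible by construction.
#'
#' @param expr cells x genes Log2Ex matrix.
#' @param meta cell metadata covering every row of `expr`.
#' @param cfg [subgroup_config()]
#' @return named list (one element per subset): `NULL` or a list with
#'   `members`, `separation`, `sizes`, `de`.
#' @export
find_subgroups <- function(expr, meta, cfg = subgroup_config()) {
  expr <- as.matrix(expr)
  sub <- .check_subsets(meta$subset[match(rownames(expr), meta$cell_id)])
  out <- list()
  for (s in SUBSET_LEVELS) {
    cells <- rownames(expr)[sub == s]
    if (length(cells) < 2L * cfg$min_subgroup_size) { out[s] <- list(NULL); next }
    pca <- run_pca(expr[cells, , drop = FALSE])
    sel <- select_subgroup(pca, cells, cfg)
    if (is.null(sel)) { out[s] <- list(NULL); next }
    sel$de <- subgroup_de(expr, sel$members, setdiff(cells, sel$members), cfg)
    out[[s]] <- sel
  }
  out
}
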