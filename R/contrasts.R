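.SUBSET_PAIRS <- list(C_vs_I  = c("classical", "intermediate"),
                      C_vs_NC = c("classical", "non_classical"),
                      I_vs_NC = c("intermediate", "non_classical"))

# two-sample t handling degenerate zero-variance strata explicitly
.safe_t <- function(a, b, var.equal = TRUE) {
  fc <- mean(a) - mean(b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, log2fc = fc, degenerate = TRUE))
    return(list(t = sign(fc) * Inf, p = .Machine$double.xmin, log2fc = fc,
                degenerate = TRUE))
  }
  tt <- tryCatch(stats::t.test(a, b, var.equal = var.equal),
                 error = function(e) NULL)
  if (is.null(tt))  # essentially-constant data inside t.test
    return(list(t = sign(fc) * Inf, p = .Machine$double.xmin, log2fc = fc,
                degenerate = TRUE))
  list(t = unname(tt$statistic), p = tt$p.value, log2fc = fc,
       degenerate = FALSE)
}

#' Pairwise subset contrasts
#'
#' For every gene and each of the three subset pairs
#' (classical vs intermediate, classical vs non-classical, intermediate vs
#' non-classical), a two-sided two-sample Student t-test on zero-inclusive
#' Log2Ex, with the log2 fold change as the difference of group means
#' (values are already on the log2 scale). The equal-variance Student test
#' is the default; set `welch = TRUE` for the unequal-variance form.
#'
#' Degenerate strata are defined explicitly: when both groups have zero
#' variance, equal means give `t = 0, p = 1` and unequal means give
#' `p` at the smallest representable positive double, both flagged via the
#' `degenerate` column.
#'
#' @param expr cells x genes Log2Ex matrix.
#' @param meta cell metadata covering every row of `expr`.
#' @param welch use the Welch unequal-variance test?
#' @return data.frame with columns `gene`, `pair`, `mean_a`, `mean_b`, `t`,
#'   `p`, `log2fc`, `degenerate`.
#' @export
pairwise_subset_tests <- function(expr, meta, welch = FALSE) {
  expr <- as.matrix(expr)
  sub <- .check_subsets(meta$subset[match(rownames(expr), meta$cell_id)])
  .assert(!anyNA(sub), "every cell must have a subset label")
  counts <- table(sub)
  .assert(all(counts >= 2L), "subset with < 2 cells: ",
          paste(names(counts)[counts < 2L], collapse = ", "))
  rows <- vector("list", ncol(expr) * 3L)
  i <- 0L
  for (g in colnames(expr)) {
    for (pn in names(.SUBSET_PAIRS)) {
      pr <- .SUBSET_PAIRS[[pn]]
      a <- expr[sub == pr[1L], g]
      b <- expr[sub == pr[2L], g]
      r <- .safe_t(a, b, var.equal = !welch)
      i <- i + 1L
      rows[[i]] <- data.frame(gene = g, pair = pn, mean_a = mean(a),
                              mean_b = mean(b), t = r$t, p = r$p,
                              log2fc = r$log2fc, degenerate = r$degenerate)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank the three subsets per gene
#'
#' Assigns highest / medium / lowest labels to the three subset means of
#' each gene. Tied subsets share the higher of the labels they span and the
#' gene is flagged.
#'
#' @param means subset-mean table from [subset_mean_table()].
#' @return data.frame with columns `gene`, one label column per subset, and
#'   `tied`.
#' @export
rank_labels <- function(means) {
  lab <- c("highest", "medium", "lowest")
  m <- as.matrix(means[, SUBSET_LEVELS])
  out <- data.frame(gene = means$gene)
  rk <- t(apply(-m, 1L, rank, ties.method = "min"))
  for (j in seq_along(SUBSET_LEVELS))
    out[[SUBSET_LEVELS[j]]] <- lab[rk[, j]]
  out$tied <- apply(rk, 1L, anyDuplicated) > 0L
  out
}

#' Genes expressed by none of the subsets
#'
#' A gene counts as "not expressed" at subset level when its zero-inclusive
#' mean is exactly 0, i.e. every cell of the subset was below the detection
#' limit.
#'
#' @param means subset-mean table.
#' @return character vector of gene names.
#' @export
never_expressed <- function(means) {
  m <- as.matrix(means[, SUBSET_LEVELS])
  means$gene[rowSums(m > 0) == 0L]
}

#' Genes unexpressed in exactly one named subset
#'
#' Genes with mean exactly 0 in `subset` and strictly positive mean in both
#' other subsets.
#'
#' @param means subset-mean table.
#' @param subset one of classical / intermediate / non_classical.
#' @return character vector of gene names.
#' @export
exclusively_unexpressed_in <- function(means, subset) {
  subset <- match.arg(subset, SUBSET_LEVELS)
  m <- as.matrix(means[, SUBSET_LEVELS])
  others <- setdiff(SUBSET_LEVELS, subset)
  means$gene[m[, subset] == 0 & rowSums(m[, others, drop = FALSE] > 0) == 2L]
}

#' Number of genes expressed in at least one subset
#'
#' @param means subset-mean table.
#' @return integer count.
#' @export
expressed_gene_count <- function(means) {
  m <- as.matrix(means[, SUBSET_LEVELS])
  sum(rowSums(m > 0) > 0L)
}

#' Group genes by functional category
#'
#' Produces a category-grouped view of the subset means with rank labels; a
#' gene may belong to several categories. Genes of `means` absent from the
#' map are reported via the `"uncategorized"` attribute.
#'
#' @param means subset-mean table.
#' @param map named list: category name -> character vector of genes.
#'   Defaults to the bundled monocyte panel categorization.
#' @return data.frame with columns `category`, `gene`, the three subset
#'   means, the three rank labels and `tied`.
#' @export
categorize <- function(means, map = monocyte_gene_categories()) {
  .assert(is.list(map), "map must be a named list of gene vectors")
  labs <- rank_labels(means)
  colnames(labs)[match(SUBSET_LEVELS, colnames(labs))] <-
    paste0("label_", SUBSET_LEVELS)
  ann <- merge(means, labs, by = "gene")
  rows <- lapply(names(map), function(cat) {
    g <- intersect(map[[cat]], means$gene)
    if (!length(g)) return(NULL)
    cbind(category = cat, ann[match(g, ann$gene), ])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "uncategorized") <- setdiff(means$gene, unlist(map))
  out
}
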