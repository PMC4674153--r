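#' Screen every gene in every subset for multimodal expression
#'
#' Computes the dip statistic and its Monte-Carlo p-value for each
#' (gene, subset) stratum of a Log2Ex matrix and flags strata with
#' `p < alpha` as multimodal. By default the dip is computed on all cells of
#' the stratum including zeros: detection-limited cells form a point mass at
#' 0, which is itself unimodal, so genes that are almost entirely
#' non-expressed come out unimodal rather than being dropped. Setting
#' `include_zeros = FALSE` restricts each stratum to expressing cells
#' (strata left with fewer than 2 such cells are skipped with `NA` results).
#'
#' @param expr cells x genes Log2Ex matrix.
#' @param meta cell metadata covering every row of `expr`.
#' @param cfg [dip_null_config()]
#' @param include_zeros include detection-limited cells (default)?
#' @return data.frame with columns `gene`, `subset`, `n`, `D`, `p`,
#'   `multimodal`, ordered gene-major then subset.
#' @export
screen_modality <- function(expr, meta, cfg = dip_null_config(),
                            include_zeros = TRUE) {
  expr <- as.matrix(expr)
  sub <- .check_subsets(meta$subset[match(rownames(expr), meta$cell_id)])
  .assert(!anyNA(sub), "every cell must have a subset label")
  counts <- table(sub)
  .assert(all(counts >= 2L), "subset with < 2 cells: ",
          paste(names(counts)[counts < 2L], collapse = ", "))
  res <- vector("list", ncol(expr) * length(SUBSET_LEVELS))
  i <- 0L
  for (g in colnames(expr)) {
    for (s in SUBSET_LEVELS) {
      x <- expr[sub == s, g]
      if (!include_zeros) x <- x[x > 0]
      i <- i + 1L
      if (length(x) < 2L) {
        res[[i]] <- data.frame(gene = g, subset = s, n = length(x),
                               D = NA_real_, p = NA_real_, multimodal = NA)
        next
      }
      D <- dip_statistic(x)
      p <- dip_pvalue(D, length(x), cfg)
      res[[i]] <- data.frame(gene = g, subset = s, n = length(x), D = D,
                             p = p, multimodal = p < cfg$alpha)
    }
  }
  out <- do.call(rbind, res)
  out$subset <- factor(out$subset, levels = SUBSET_LEVELS)
  rownames(out) <- NULL
  out
}

#' Dropout-bias diagnostic for the modality screen
#'
#' If weakly expressed genes were more dropout-prone, spurious zero-inflation
#' could masquerade as multimodality, and multimodal calls would concentrate
#' among low-expression genes. The diagnostic compares, between unimodal and
#' multimodal genes, the mean Log2Ex computed over expressing cells only
#' (zeros excluded, so the comparison is not confounded by the dropout mass
#' itself) with a two-sided two-sample Student t-test. A large p-value says
#' the two groups of genes sit at similar expression levels, i.e. no
#' evidence that the multimodal calls are a dropout artefact.
#'
#' A gene is placed in the multimodal group when it is flagged in at least
#' one of the strata present in `results`. Genes with no expressing cell are
#' excluded and reported.
#'
#' @param expr cells x genes Log2Ex matrix.
#' @param results output of [screen_modality()].
#' @return list with the per-group gene means, group sizes, `t`, `df`, `p`,
#'   and `excluded_genes`.
#' @export
dropout_bias_check <- function(expr, results) {
  expr <- as.matrix(expr)
  flag <- tapply(results$multimodal, results$gene, function(z) any(z %in% TRUE))
  genes <- intersect(colnames(expr), names(flag))
  expressed_mean <- vapply(genes, function(g) {
    v <- expr[, g]; v <- v[v > 0]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  excluded <- genes[is.na(expressed_mean)]
  keep <- !is.na(expressed_mean)
  mm <- expressed_mean[keep][flag[genes[keep]]]
  um <- expressed_mean[keep][!flag[genes[keep]]]
  .assert(length(mm) >= 2L && length(um) >= 2L,
          "need at least 2 genes in each of the unimodal and multimodal groups")
  tt <- stats::t.test(um, mm, var.equal = TRUE)
  list(mean_unimodal = mean(um), mean_multimodal = mean(mm),
       n_unimodal = length(um), n_multimodal = length(mm),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, excluded_genes = excluded)
}
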