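test_that("PCA: variance fractions, duplicated cells, sign convention", {
  with_seed(31, {
    m <- matrix(rnorm(20 * 6, 5), 20,
                dimnames = list(sprintf("c%02d", 1:20), paste0("g", 1:6)))
    m[2, ] <- m[1, ]                      # duplicated cell
    p <- run_pca(m)
    expect_equal(sum(p$variance_fraction), 1)
    expect_true(all(diff(p$variance_fraction) <= 1e-12))
    expect_equal(p$scores[1, ], p$scores[2, ])
    # sign fix: largest-magnitude loading positive in every component
    for (j in seq_len(ncol(p$loadings)))
      expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
    # scores reproduce centred data through the loadings
    rec <- p$scores %*% t(p$loadings)
    expect_equal(rec, scale(m, scale = FALSE), ignore_attr = TRUE)
  })
  # two perfectly correlated genes: one component carries everything
  m2 <- cbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8))
  rownames(m2) <- paste0("c", 1:4)
  p2 <- run_pca(m2)
  expect_equal(p2$variance_fraction[1], 1)
  expect_error(run_pca(matrix(3, 4, 2, dimnames = list(paste0("c", 1:4),
                                                       c("a", "b")))),
               "constant")
})

test_that("heatmap clustering is order-invariant and merges identical cells first", {
  with_seed(32, {
    m <- matrix(rnorm(12 * 5, 6), 12,
                dimnames = list(sprintf("c%02d", 1:12), paste0("g", 1:5)))
    m["c07", ] <- m["c03", ]
    h <- cluster_heatmap_order(m)
    merged_first <- h$cell_hclust$merge[h$cell_hclust$height == 0, ]
    expect_length(merged_first, 2L)       # exactly one zero-height merge
    perm <- sample(nrow(m))
    h2 <- cluster_heatmap_order(m[perm, sample(ncol(m))])
    expect_identical(h$cell_order, h2$cell_order)
    expect_identical(h$gene_order, h2$gene_order)
    expect_identical(h$cell_hclust$merge, h2$cell_hclust$merge)
  })
})

test_that("hierarchical merge heights match a hand-computed 3-point example", {
  m <- matrix(c(0, 1, 5, 0, 0, 0), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("g1", "g2")))
  h <- cluster_heatmap_order(m)$cell_hclust
  # complete linkage: {a,b} at height 1, then {ab, c} at max(5, 4) = 5
  expect_equal(sort(h$height), c(1, 5))
})

test_that("subgroup selection: planted blobs found, clouds rejected, order-invariant", {
  with_seed(33, {
    # 80 + 14 cells, centroid distance 10x the within-sd
    sc <- rbind(matrix(rnorm(80 * 2, 0, 1), 80),
                matrix(rnorm(14 * 2, 10, 1), 14))
    rownames(sc) <- sprintf("c%02d", 1:94)
    colnames(sc) <- c("PC1", "PC2")
    p <- structure(list(scores = sc, variance_fraction = c(.6, .4)),
                   class = "scq_pca")
    sel <- select_subgroup(p, rownames(sc))
    expect_setequal(sel$members, sprintf("c%02d", 81:94))
    expect_gt(sel$separation, 0.45)
    # invariance to the order of the cell list
    sel2 <- select_subgroup(p, rev(rownames(sc)))
    expect_identical(sel2$members, sel$members)
    expect_error(select_subgroup(p, rownames(sc)[1:9]), "too few")
  })
  # a single structureless cloud yields no subgroup in almost all runs
  with_seed(34, {
    rejected <- sum(vapply(1:40, function(i) {
      sc <- matrix(rnorm(90 * 2), 90,
                   dimnames = list(sprintf("c%02d", 1:90), c("PC1", "PC2")))
      p <- structure(list(scores = sc, variance_fraction = c(.5, .5)),
                     class = "scq_pca")
      is.null(select_subgroup(p, rownames(sc)))
    }, NA))
    expect_gte(rejected, 38L)             # >= 95%
  })
})

test_that("subgroup DE applies both thresholds and reports directions", {
  with_seed(35, {
    cells <- sprintf("c%02d", 1:40)
    members <- cells[1:8]; rest <- cells[9:40]
    m <- matrix(rnorm(40 * 4, 5, 0.2), 40,
                dimnames = list(cells, c("up2", "small_p", "down2", "null")))
    m[members, "up2"] <- m[members, "up2"] + 2
    m[members, "down2"] <- m[members, "down2"] - 2
    # tiny p but |fc| < 1: must be excluded by the fold-change arm
    m[, "small_p"] <- rnorm(40, 5, 0.01)
    m[members, "small_p"] <- m[members, "small_p"] + 0.5
    de <- subgroup_de(m, members, rest)
    expect_setequal(de$gene, c("up2", "down2"))
    expect_equal(de$direction[de$gene == "up2"], "up")
    expect_equal(de$direction[de$gene == "down2"], "down")
    expect_true(all(de$p < 0.05 & abs(de$log2fc) >= 1))
  })
})

test_that("identical distributions give an empty DE list", {
  cells <- sprintf("c%02d", 1:20)
  m <- matrix(rep(c(5, 1), each = 20), 20,
              dimnames = list(cells, c("gA", "gB")))
  de <- subgroup_de(m, cells[1:5], cells[6:20])
  expect_equal(nrow(de), 0L)
  expect_error(subgroup_de(m, cells[1], cells[2:20]), ">= 2")
})
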