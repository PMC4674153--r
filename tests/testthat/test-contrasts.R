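three_group_expr <- function(vals_by_subset, gene = "g1") {
  n <- vapply(vals_by_subset, length, 0L)
  cells <- sprintf("c%02d", seq_len(sum(n)))
  meta <- cell_meta(cells, rep(names(vals_by_subset), n))
  m <- matrix(unlist(vals_by_subset), ncol = 1,
              dimnames = list(cells, gene))
  list(expr = m, meta = meta)
}

test_that("pairwise tests: schema, identical groups, degenerate strata", {
  d <- three_group_expr(list(classical = c(1, 2, 3),
                             intermediate = c(1, 2, 3),
                             non_classical = c(5, 5, 5)))
  res <- pairwise_subset_tests(d$expr, d$meta)
  expect_equal(res$pair, c("C_vs_I", "C_vs_NC", "I_vs_NC"))
  ci <- res[res$pair == "C_vs_I", ]
  expect_equal(ci$t, 0)
  expect_equal(ci$p, 1)
  expect_equal(ci$log2fc, 0)
  # one constant group against a varying one still works via t.test
  cnc <- res[res$pair == "C_vs_NC", ]
  expect_equal(cnc$log2fc, 2 - 5)
  expect_lt(cnc$p, 1)

  # both groups constant and different: flagged degenerate, p at the floor
  d2 <- three_group_expr(list(classical = c(0, 0, 0, 0),
                              intermediate = c(5, 5, 5, 5),
                              non_classical = c(1, 2, 3, 4)))
  r2 <- pairwise_subset_tests(d2$expr, d2$meta)
  deg <- r2[r2$pair == "C_vs_I", ]
  expect_true(deg$degenerate)
  expect_equal(deg$p, .Machine$double.xmin)
  expect_equal(deg$log2fc, -5)
})

test_that("swapping a pair negates t and log2fc and preserves p", {
  with_seed(21, {
    d <- three_group_expr(list(classical = rnorm(8, 3),
                               intermediate = rnorm(9, 5),
                               non_classical = rnorm(7, 4)))
    res <- pairwise_subset_tests(d$expr, d$meta)
    ci <- res[res$pair == "C_vs_I", ]
    swapped <- .safe_t(d$expr[d$meta$subset == "intermediate", 1],
                       d$expr[d$meta$subset == "classical", 1])
    expect_equal(swapped$t, -ci$t)
    expect_equal(swapped$log2fc, -ci$log2fc)
    expect_equal(swapped$p, ci$p)
  })
})

test_that("Student vs Welch are both available and differ when variances do", {
  with_seed(22, {
    d <- three_group_expr(list(classical = rnorm(20, 5, 0.2),
                               intermediate = rnorm(20, 6, 3),
                               non_classical = rnorm(20, 5, 1)))
    s <- pairwise_subset_tests(d$expr, d$meta)
    w <- pairwise_subset_tests(d$expr, d$meta, welch = TRUE)
    expect_false(isTRUE(all.equal(s$p[s$pair == "C_vs_I"],
                                  w$p[w$pair == "C_vs_I"])))
  })
})

test_that("rank labels order subsets per gene and flag ties", {
  means <- data.frame(gene = c("CD14-like", "tieHigh", "allEqual"),
                      classical = c(11.7, 1, 2),
                      intermediate = c(7.3, 2, 2),
                      non_classical = c(4.6, 2, 2))
  r <- rank_labels(means)
  expect_equal(r$classical[1], "highest")
  expect_equal(r$intermediate[1], "medium")
  expect_equal(r$non_classical[1], "lowest")
  expect_false(r$tied[1])
  # ties share the higher label
  expect_equal(r$intermediate[2], "highest")
  expect_equal(r$non_classical[2], "highest")
  expect_equal(r$classical[2], "lowest")
  expect_true(r$tied[2])
  expect_equal(unlist(r[3, SUBSET_LEVELS], use.names = FALSE),
               rep("highest", 3))
  expect_true(r$tied[3])
})

test_that("presence filters on the bundled reference table match its text", {
  t2 <- monocyte_subset_means()
  expect_equal(nrow(t2), 85L)
  expect_setequal(never_expressed(t2),
                  c("CCR7", "MMP12", "MRC1", "ULBP1", "ULBP2"))
  expect_setequal(exclusively_unexpressed_in(t2, "non_classical"),
                  c("CCR2", "CD163", "CLEC4E", "SERPINB2"))
  # CCR5 is zero in classical too, so it must not count as exclusive
  expect_false("CCR5" %in% exclusively_unexpressed_in(t2, "non_classical"))
  expect_equal(expressed_gene_count(t2), 80L)
  # partition property
  expect_equal(expressed_gene_count(t2) + length(never_expressed(t2)),
               nrow(t2))
  for (s in SUBSET_LEVELS)
    expect_length(intersect(never_expressed(t2),
                            exclusively_unexpressed_in(t2, s)), 0L)
})

test_that("presence filters behave on constructed tables", {
  tb <- data.frame(gene = paste0("g", 1:4),
                   classical = c(0, 1, 0, 2),
                   intermediate = c(0, 1, 3, 2),
                   non_classical = c(0, 1, 4, 0))
  expect_equal(never_expressed(tb), "g1")
  expect_equal(exclusively_unexpressed_in(tb, "classical"), "g3")
  expect_equal(exclusively_unexpressed_in(tb, "non_classical"), "g4")
  expect_equal(expressed_gene_count(tb), 3L)
  all_pos <- tb; all_pos[, -1] <- 1
  expect_length(never_expressed(all_pos), 0L)
  expect_length(exclusively_unexpressed_in(all_pos, "classical"), 0L)
})

test_that("categorization groups genes and reports unknowns", {
  t2 <- monocyte_subset_means()
  cats <- categorize(t2)
  expect_true(all(c("IL10", "TNF") %in%
                    cats$gene[cats$category == "cytokines"]))
  # CD93 sits in two categories
  expect_gte(sum(cats$gene == "CD93"), 2L)
  # every categorized gene is in the panel
  expect_true(all(cats$gene %in% t2$gene))
  # housekeeping plus the five never-expressed genes carry no category
  expect_setequal(attr(cats, "uncategorized"),
                  c("ACTB", "CCR7", "MMP12", "MRC1", "ULBP1", "ULBP2"))
  out <- categorize(t2, map = list(tiny = "CD14"))
  expect_equal(nrow(out), 1L)
  expect_equal(length(attr(out, "uncategorized")), 84L)
})
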