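test_that("simulation is exactly reproducible per seed", {
  cfg <- sim_config(seed = 7, genes = gene_specs_from_means(sd = 1))
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$ct$ct, b$ct$ct)
  expect_identical(a$truth$log2ex, b$truth$log2ex)
  expect_identical(a$meta, b$meta)
  c2 <- simulate_experiment(sim_config(seed = 8,
                                       genes = gene_specs_from_means(sd = 1)))
  expect_false(identical(a$ct$ct, c2$ct$ct))
})

test_that("disabling dropout and empty wells detects every target reaction", {
  specs <- lapply(1:10, function(i) gene_spec(sprintf("G%02d", i),
                                              mu = 6 + i / 2, sd = 0.5))
  cfg <- sim_config(n_cells = c(classical = 20, intermediate = 20,
                                non_classical = 20),
                    genes = specs, empty_well_rate = 0,
                    dropout_midpoint = -Inf, seed = 3)
  sim <- simulate_experiment(cfg)
  targets <- setdiff(sim$ct$assay_ids, "18S")
  expect_false(anyNA(sim$ct$ct[, targets]))
  expect_length(sim$truth$empty_wells, 0L)
  expect_false(any(sim$truth$dropout))
})

test_that("bimodal genes produce the configured component split", {
  specs <- list(gene_spec("bi", mu = 5, sd = 0.3, modality = "bimodal",
                          mu1 = 2, mu2 = 8, pi = 0.5))
  cfg <- sim_config(n_cells = c(classical = 400, intermediate = 300,
                                non_classical = 300),
                    genes = specs, empty_well_rate = 0,
                    dropout_midpoint = -Inf, seed = 11)
  sim <- simulate_experiment(cfg)
  x <- sim$truth$log2ex[, "bi"]
  upper <- mean(x > 5)
  expect_lt(abs(upper - 0.5), 3 * sqrt(0.25 / 1000))
  expect_equal(sim$truth$genes$modality, "bimodal")
})

test_that("dropout probability decreases with true expression", {
  specs <- lapply(1:8, function(i) gene_spec(sprintf("G%02d", i),
                                             mu = i, sd = 2))
  cfg <- sim_config(n_cells = c(classical = 500, intermediate = 500,
                                non_classical = 500),
                    genes = specs, empty_well_rate = 0, seed = 5)
  sim <- simulate_experiment(cfg)
  x <- as.vector(sim$truth$log2ex)
  dr <- as.vector(sim$truth$dropout)
  bins <- cut(x, c(-0.01, 1, 2, 3, 4, 5, 6, Inf))
  rate <- tapply(dr, bins, mean)
  expect_true(all(diff(rate) <= 0.02))   # non-increasing up to noise
  # dropout implies the emitted value is the nondetect marker
  targets <- setdiff(sim$ct$assay_ids, "18S")
  expect_true(all(is.na(sim$ct$ct[, targets][sim$truth$dropout])))
})

test_that("pipeline closure: detected Log2Ex is recovered within noise", {
  specs <- lapply(1:20, function(i) gene_spec(sprintf("G%02d", i),
                                              mu = 4 + i / 4, sd = 1.5))
  cfg <- sim_config(genes = specs, seed = 13, ct_noise_sd = 0.5)
  sim <- simulate_experiment(cfg)
  flt <- filter_empty_wells(sim$ct)
  expr <- ct_to_log2ex(flt$ct, norm_config(lod_ct = cfg$lod_ct))
  truth <- sim$truth$log2ex[rownames(expr), colnames(expr)]
  det <- !sim$truth$dropout[rownames(expr), colnames(expr)]
  rmse <- sqrt(mean((expr[det] - truth[det])^2))
  expect_lte(rmse, 2 * cfg$ct_noise_sd)
})

test_that("recovery metrics are exact on perfect and empty predictions", {
  cfg <- recovery_study_config(2)
  sim <- simulate_experiment(cfg)
  truth <- sim$truth
  members <- truth$cells$cell_id[truth$cells$in_subgroup]
  perfect <- evaluate_recovery(truth,
                               subgroup = list(members = members),
                               de = data.frame(gene = cfg$subgroup$genes),
                               planted = cfg$subgroup)
  expect_equal(perfect$subgroup_ari, 1)
  expect_equal(perfect$de_precision, 1)
  expect_equal(perfect$de_recall, 1)
  none <- evaluate_recovery(truth, subgroup = NULL,
                            de = data.frame(gene = character(0)),
                            planted = cfg$subgroup)
  expect_lte(none$subgroup_ari, 0)
  expect_equal(none$de_recall, 0)
  # modality confusion on labelled truth
  dipres <- data.frame(gene = rep(truth$genes$gene, each = 1),
                       multimodal = truth$genes$modality == "bimodal")
  m <- evaluate_recovery(truth, dip_results = dipres)
  expect_equal(m$modality_specificity, 1)
})
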