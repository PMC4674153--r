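# Shared study configurations for recovery tests.

# Planted-subgroup study: 40 expressed genes (means 5-12 Log2Ex, sd 1.5),
# a subgroup of 15% of the classical cells with 20 genes shifted +2.
recovery_study_config <- function(seed) {
  with_seed(seed + 1000, {
    mu <- stats::runif(40, 5, 12)
    specs <- lapply(seq_along(mu), function(i)
      gene_spec(sprintf("G%02d", i), mu[i], sd = 1.5))
    sim_config(seed = seed, genes = specs,
               subgroup = list(subset = "classical", fraction = 0.15,
                               genes = sprintf("G%02d", 1:20), shift = 2))
  })
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# small deterministic ct_table for io tests
tiny_ct <- function() {
  m <- matrix(c(20, 21, 22,
                18, NA, 19,
                25, 26, 24), nrow = 3, byrow = TRUE,
              dimnames = list(c("c1", "c2", "c3"), c("ACTB", "CD14", "18S")))
  ct_table(m)
}

tiny_meta <- function() cell_meta(c("c1", "c2", "c3"),
                                  c("classical", "intermediate",
                                    "non_classical"))
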