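# Regenerates tests/testthat/dip_reference_minsup.tsv: a frozen set of
# samples whose dip values were computed by exact linear programming over
# piecewise-linear unimodal CDFs (lp_dip.py, scipy/HiGHS), independent of
# any code in R/. Run from the package root; requires python with scipy.
set.seed(2026)
samples <- list(c(0, 1), c(0, 0.5, 1), c(3, 3, 3, 3, 3), c(0, 0, 1),
                c(0, 0, 0, 1, 1, 1))
for (r in 1:245) {
  n <- sample(2:40, 1)
  kind <- sample(6, 1)
  x <- switch(kind,
    round(runif(n), sample(0:2, 1)),
    { nz <- sample(0:(n - 1), 1); c(rep(0, nz), round(runif(n - nz) * 8, 2)) },
    round(c(rnorm(ceiling(n / 2), 0), rnorm(floor(n / 2), sample(2:8, 1))), 3),
    sample(0:3, n, replace = TRUE),
    rep(sample(1:3, 2), length.out = n),
    round(cumsum(abs(rnorm(n))), 3))
  samples[[length(samples) + 1]] <- x
}
json <- paste0("[", paste(vapply(samples, function(s)
  paste0("[", paste(format(s, digits = 17), collapse = ","), "]"), ""),
  collapse = ","), "]")
tf <- tempfile(); writeLines(json, tf)
lp <- as.numeric(jsonlite::fromJSON(system(
  paste("python data-raw/lp_dip.py <", tf), intern = TRUE)))
tab <- data.frame(
  sample = vapply(samples, function(s) paste(format(s, digits = 15),
                                             collapse = ","), ""),
  dip = format(lp, digits = 17))
write.table(tab, "tests/testthat/dip_reference_minsup.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
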