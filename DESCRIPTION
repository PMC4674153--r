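Package: scqmod
Title: Heterogeneity Analysis for Single-Cell qPCR Expression Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-cell qPCR gene-expression panels
    measured on sorted immune-cell subsets, as produced by microfluidic
    (BioMark-style) instruments. Converts raw cycle-threshold matrices into
    nonnegative limit-of-detection expression values (Log2Ex), filters empty
    wells by a ribosomal-RNA control, screens every gene in every cell subset
    for multimodal expression with Hartigan's dip statistic calibrated by
    Monte Carlo against the uniform null, computes pairwise subset contrasts
    and expression-presence summaries, and discovers minority subgroups of
    cells within a subset from principal-component scores with a fixed
    differential-expression rule (p < 0.05 and |log2 fold change| >= 1).
    Includes a seeded generator of synthetic Ct-level experiments with
    expression-dependent dropout, empty wells, bimodal genes and planted
    subgroups, plus bundled reference summary tables for an 85-gene human
    monocyte panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    cluster,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
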