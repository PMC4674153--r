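.extdata <- function(f) {
  p <- system.file("extdata", f, package = "scqmod")
  if (p == "") p <- file.path("inst", "extdata", f)   # pre-install fallback
  .assert(file.exists(p), "bundled file not found: ", f)
  p
}

#' Bundled per-gene subset means of the monocyte reference panel
#'
#' Published summary of an 85-gene single-cell qPCR panel profiled on sorted
#' classical, intermediate and non-classical human blood monocytes:
#' zero-inclusive mean Log2Ex per gene and subset, plus the pairwise
#' t-test p-values between subsets (NA where no test was reported). Values
#' are transcribed at the printed precision (one decimal for means, two
#' significant digits for p-values); decimal commas of the source were
#' normalized to points at transcription time.
#'
#' @return data.frame with columns `gene`, `classical`, `intermediate`,
#'   `non_classical`, `p_C_vs_I`, `p_C_vs_NC`, `p_I_vs_NC`.
#' @export
monocyte_subset_means <- function() {
  utils::read.table(.extdata("monocyte_subset_means.tsv"), sep = "\t",
                    header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Bundled per-gene modality p-values of the monocyte reference panel
#'
#' Published dip-test p-values per gene and subset (printed at two
#' decimals) with the published multimodality flags. The five genes of the
#' panel expressed by no subset carry no modality entry and are absent
#' (80 rows).
#'
#' @return data.frame with columns `gene`, the three subset p-values and
#'   the three 0/1 flag columns.
#' @export
monocyte_modality_pvalues <- function() {
  utils::read.table(.extdata("monocyte_modality_pvalues.tsv"), sep = "\t",
                    header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Bundled functional categorization of the monocyte panel
#'
#' @return named list mapping category names to gene vectors.
#' @export
monocyte_gene_categories <- function() {
  yaml::read_yaml(.extdata("monocyte_gene_categories.yaml"))
}

#' Gene names of the bundled 85-gene monocyte panel
#'
#' Includes the ACTB housekeeping assay; the 18S well control is not a
#' panel member.
#'
#' @return character vector of 85 gene symbols.
#' @export
monocyte_panel_genes <- function() monocyte_subset_means()$gene

#' Consistency checks of the bundled reference tables
#'
#' Recomputes, from the bundled tables alone, the headline counts of the
#' reference monocyte data set: the number of multimodal genes per subset
#' (counting printed p-values at or below 0.05 at their two-decimal
#' precision -- a printed "0.05" is flagged in the source, so the fixture
#' counting rule is `<=` while the live screen of [screen_modality()] uses
#' strict `<`), the never-expressed gene set, the genes unexpressed
#' exclusively in the non-classical subset, and the number of genes
#' expressed in at least one subset.
#'
#' @param expected named list of expected values (defaults to the published
#'   counts).
#' @param stop_on_mismatch error if any check fails?
#' @return data.frame with one row per check: `check`, `value`, `expected`,
#'   `ok`.
#' @export
check_fixtures <- function(expected = list(multimodal_classical = 37,
                                           multimodal_intermediate = 39,
                                           multimodal_non_classical = 36,
                                           n_never_expressed = 5,
                                           n_exclusive_non_classical = 4,
                                           n_expressed = 80),
                           stop_on_mismatch = FALSE) {
  t2 <- monocyte_subset_means()
  t4 <- monocyte_modality_pvalues()
  tol <- 1e-9     # printed two-decimal values; <= at printed precision
  got <- list(
    multimodal_classical = sum(t4$classical <= 0.05 + tol),
    multimodal_intermediate = sum(t4$intermediate <= 0.05 + tol),
    multimodal_non_classical = sum(t4$non_classical <= 0.05 + tol),
    n_never_expressed = length(never_expressed(t2)),
    n_exclusive_non_classical =
      length(exclusively_unexpressed_in(t2, "non_classical")),
    n_expressed = expressed_gene_count(t2))
  out <- data.frame(check = names(expected),
                    value = unlist(got[names(expected)]),
                    expected = unlist(expected),
                    row.names = NULL)
  out$ok <- out$value == out$expected
  if (stop_on_mismatch && !all(out$ok))
    stop("fixture check failed: ",
         paste(out$check[!out$ok], collapse = ", "), call. = FALSE)
  out
}
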