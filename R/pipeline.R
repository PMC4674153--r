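#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end on a raw Ct table: empty-well
#' filtering, the Log2Ex transform (and optional normalization), subset
#' means, pairwise contrasts, presence filters, the modality screen, and
#' subgroup discovery. Every stage output is written as TSV into `out_dir`
#' together with a manifest of file checksums and the settings used, so a
#' rerun with identical inputs and configuration is byte-identical.
#'
#' @param ct [ct_table()] or path to a Ct file (then read with `dialect`).
#' @param meta cell metadata data.frame or path to a metadata TSV.
#' @param out_dir output directory (created if needed).
#' @param dialect dialect used when `ct` is a path.
#' @param panel [panel_spec()]
#' @param norm [norm_config()]
#' @param dip [dip_null_config()]
#' @param subgroups [subgroup_config()]
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest` (the manifest data.frame).
#' @export
run_pipeline <- function(ct, meta, out_dir,
                         dialect = c("wide", "long"),
                         panel = panel_spec(),
                         norm = norm_config(),
                         dip = dip_null_config(B = 2000),
                         subgroups = subgroup_config()) {
  if (is.character(ct)) ct <- read_ct_table(ct, match.arg(dialect))
  if (is.character(meta)) meta <- read_cell_meta(meta)
  .assert(inherits(ct, "ct_table"), "ct must be a ct_table or a path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  flt <- filter_empty_wells(ct, panel)
  meta_kept <- join_metadata(flt$ct, meta, strict = FALSE)
  expr <- ct_to_log2ex(flt$ct, norm)
  expr <- normalize_expression(expr, norm, meta_kept)
  means <- subset_mean_table(expr, meta_kept)
  contrasts <- pairwise_subset_tests(expr, meta_kept)
  modality <- screen_modality(expr, meta_kept, dip)
  bias <- tryCatch(dropout_bias_check(expr, modality), error = function(e) NULL)
  subs <- find_subgroups(expr, meta_kept, subgroups)

  w <- function(df, f) {
    utils::write.table(df, file.path(out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    f
  }
  files <- c(
    w(data.frame(cell_id = flt$removed_cell_ids), "removed_wells.tsv"),
    w(data.frame(cell_id = rownames(expr), expr, check.names = FALSE),
      "log2ex.tsv"),
    w(means, "subset_means.tsv"),
    w(contrasts, "contrasts.tsv"),
    w(modality, "modality.tsv"))
  sub_rows <- lapply(names(subs), function(s) {
    if (is.null(subs[[s]])) return(NULL)
    data.frame(subset = s, cell_id = subs[[s]]$members)
  })
  files <- c(files, w(do.call(rbind, sub_rows) %||%
                        data.frame(subset = character(0),
                                   cell_id = character(0)),
                      "subgroup_members.tsv"))
  de_rows <- lapply(names(subs), function(s) {
    if (is.null(subs[[s]]) || !nrow(subs[[s]]$de)) return(NULL)
    cbind(subset = s, subs[[s]]$de)
  })
  files <- c(files, w(do.call(rbind, de_rows) %||%
                        data.frame(subset = character(0), gene = character(0),
                                   log2fc = numeric(0), p = numeric(0),
                                   direction = character(0)),
                      "subgroup_de.tsv"))

  settings <- c(lod_ct = norm$lod_ct, norm_mode = norm$mode,
                control_max_ct = panel$control_max_ct,
                dip_B = dip$B, dip_seed = dip$seed, alpha = dip$alpha,
                de_alpha = subgroups$alpha,
                min_abs_log2fc = subgroups$min_abs_log2fc)
  manifest <- data.frame(
    file = c(files, "settings"),
    md5 = c(unname(tools::md5sum(file.path(out_dir, files))),
            substr(paste(names(settings), settings, collapse = ";"), 1, 1e6)))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(ct = flt$ct, removed = flt$removed_cell_ids, expr = expr,
                 means = means, contrasts = contrasts, modality = modality,
                 dropout_bias = bias, subgroups = subs, manifest = manifest))
}
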