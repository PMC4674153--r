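#' Cycle-threshold (Ct) table
#'
#' Container for a cells-by-assays matrix of raw qPCR cycle-threshold values.
#' Non-detected reactions (no amplification signal) are stored as `NA`, the
#' internal nondetect marker. Every observed Ct must be finite and positive.
#'
#' @param ct numeric matrix (cells in rows, assays in columns); `NA` marks a
#'   nondetect.
#' @param cell_ids,assay_ids character vectors of unique identifiers; taken
#'   from `dimnames(ct)` when omitted.
#' @return An object of class `ct_table`: a list with elements `cell_ids`,
#'   `assay_ids` and the numeric matrix `ct`.
#' @export
ct_table <- function(ct, cell_ids = rownames(ct), assay_ids = colnames(ct)) {
  ct <- as.matrix(ct)
  storage.mode(ct) <- "double"
  .assert(!is.null(cell_ids) && !is.null(assay_ids),
          "cell_ids and assay_ids are required (or supply dimnames)")
  cell_ids <- as.character(cell_ids)
  assay_ids <- as.character(assay_ids)
  .assert(!anyDuplicated(cell_ids), "duplicate cell ids")
  .assert(!anyDuplicated(assay_ids), "duplicate assay ids")
  .assert(nrow(ct) == length(cell_ids) && ncol(ct) == length(assay_ids),
          "matrix dimensions do not match id lists")
  obs <- ct[!is.na(ct)]
  .assert(all(is.finite(obs)), "non-finite Ct value")
  .assert(all(obs > 0), "Ct values must be > 0")
  dimnames(ct) <- list(cell_ids, assay_ids)
  structure(list(cell_ids = cell_ids, assay_ids = assay_ids, ct = ct),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("<ct_table> %d cells x %d assays, %.1f%% nondetect\n",
              length(x$cell_ids), length(x$assay_ids),
              100 * mean(is.na(x$ct))))
  invisible(x)
}

#' Assay panel description
#'
#' Describes the assay layout of a single-cell qPCR run: the target-gene
#' panel, the housekeeping reference, and the well-occupancy control assay
#' with its Ct ceiling. A well whose control assay gives no signal, or a
#' signal above `control_max_ct` cycles, is treated as empty (no cell).
#'
#' @param target_genes character vector of target assay names. Defaults to
#'   the bundled 85-gene monocyte panel.
#' @param housekeeping_gene reference assay, must be one of `target_genes`.
#' @param well_control_gene occupancy-control assay, must not be a target.
#' @param control_max_ct Ct ceiling (cycles) for the control assay; the rule
#'   is strict ("above"), so a control Ct exactly at the ceiling is kept.
#' @return list of class `panel_spec`.
#' @export
panel_spec <- function(target_genes = monocyte_panel_genes(),
                       housekeeping_gene = "ACTB",
                       well_control_gene = "18S",
                       control_max_ct = 40) {
  target_genes <- as.character(target_genes)
  .assert(!anyDuplicated(target_genes), "duplicate target genes")
  .assert(housekeeping_gene %in% target_genes,
          "housekeeping gene must be part of the target panel")
  .assert(!well_control_gene %in% target_genes,
          "well-control assay must not be a target gene")
  .assert(is.numeric(control_max_ct) && control_max_ct > 0,
          "control_max_ct must be > 0")
  structure(list(target_genes = target_genes,
                 housekeeping_gene = housekeeping_gene,
                 well_control_gene = well_control_gene,
                 control_max_ct = control_max_ct),
            class = "panel_spec")
}

.parse_ct_values <- function(x, nondetect_values) {
  x <- trimws(as.character(x))
  x[x %in% nondetect_values] <- NA
  suppressWarnings(v <- as.numeric(x))
  bad <- !is.na(x) & is.na(v)
  v[bad] <- NA          # unparseable cells are nondetects
  v
}

#' Read a Ct table from a delimited file
#'
#' Two dialects are supported. `wide`: one row per cell, first column the
#' cell id, remaining columns one assay each. `long`: three columns
#' (cell, assay, ct), one row per reaction. Field separator is inferred from
#' the file extension (`.csv` vs anything else = tab). Empty fields, `NA`,
#' and the instrument sentinel `999` (a common export convention for failed
#' reactions) are read as nondetects; additional sentinels can be supplied.
#'
#' @param path file path.
#' @param dialect `"wide"` or `"long"`.
#' @param nondetect_values character vector of field values mapped to the
#'   nondetect marker.
#' @return [ct_table()]
#' @export
read_ct_table <- function(path, dialect = c("wide", "long"),
                          nondetect_values = c("", "NA", "999")) {
  dialect <- match.arg(dialect)
  .assert(file.exists(path), "file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (dialect == "wide") {
    .assert(ncol(df) >= 2L, "wide table needs a cell-id column plus assays")
    cells <- df[[1L]]
    assays <- colnames(df)[-1L]
    m <- vapply(df[-1L], .parse_ct_values, numeric(nrow(df)),
                nondetect_values = nondetect_values)
    m <- matrix(m, nrow = nrow(df), dimnames = list(cells, assays))
    neg <- !is.na(m) & m <= 0
    .assert(!any(neg), "nonpositive Ct value in ", path)
    ct_table(m, cells, assays)
  } else {
    .assert(ncol(df) >= 3L, "long table needs columns cell, assay, ct")
    cells <- unique(df[[1L]])
    assays <- unique(df[[2L]])
    key <- paste(df[[1L]], df[[2L]], sep = "\r")
    dup <- key[duplicated(key)]
    .assert(length(dup) == 0L, "duplicate (cell, assay) pair(s): ",
            paste(gsub("\r", "/", utils::head(dup, 3L)), collapse = ", "))
    v <- .parse_ct_values(df[[3L]], nondetect_values)
    .assert(!any(!is.na(v) & v <= 0), "nonpositive Ct value in ", path)
    m <- matrix(NA_real_, length(cells), length(assays),
                dimnames = list(cells, assays))
    m[cbind(match(df[[1L]], cells), match(df[[2L]], assays))] <- v
    ct_table(m, cells, assays)
  }
}

#' Write a Ct table to a delimited file
#'
#' Inverse of [read_ct_table()]; values are written with full double
#' precision so that a write/read round trip reproduces the table exactly.
#' Nondetects are written as `NA`.
#'
#' @param x [ct_table()]
#' @param path output path; `.csv` gives comma separation, otherwise tab.
#' @param dialect `"wide"` or `"long"`.
#' @export
write_ct_table <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  .assert(inherits(x, "ct_table"), "x must be a ct_table")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  if (dialect == "wide") {
    body <- apply(x$ct, 1L, function(r) paste(fmt(r), collapse = sep))
    lines <- c(paste(c("cell_id", x$assay_ids), collapse = sep),
               paste(x$cell_ids, body, sep = sep))
  } else {
    idx <- expand.grid(cell = seq_along(x$cell_ids),
                       assay = seq_along(x$assay_ids))
    lines <- c(paste(c("cell_id", "assay_id", "ct"), collapse = sep),
               paste(x$cell_ids[idx$cell], x$assay_ids[idx$assay],
                     fmt(x$ct[cbind(idx$cell, idx$assay)]), sep = sep))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Remove empty wells using the occupancy-control assay
#'
#' A well is empty when its control assay (18S by default) has no Ct value or
#' a Ct value strictly above the ceiling. Empty wells are removed and the
#' control assay column is dropped from the returned table; the order of the
#' surviving cells is preserved. The filter is idempotent: on a table that
#' has already been filtered (control column absent) it is the identity.
#'
#' @param ct [ct_table()] containing the control assay.
#' @param spec [panel_spec()]
#' @return list with elements `ct` (filtered table, control column dropped)
#'   and `removed_cell_ids`.
#' @export
filter_empty_wells <- function(ct, spec = panel_spec()) {
  .assert(inherits(ct, "ct_table"), "ct must be a ct_table")
  ctrl <- spec$well_control_gene
  if (!ctrl %in% ct$assay_ids && isTRUE(attr(ct, "wells_filtered")))
    return(list(ct = ct, removed_cell_ids = character(0)))
  .assert(ctrl %in% ct$assay_ids, "control assay '", ctrl, "' not in table")
  v <- ct$ct[, ctrl]
  empty <- is.na(v) | v > spec$control_max_ct
  keep_assays <- setdiff(ct$assay_ids, ctrl)
  out <- ct_table(ct$ct[!empty, keep_assays, drop = FALSE],
                  ct$cell_ids[!empty], keep_assays)
  attr(out, "wells_filtered") <- TRUE
  list(ct = out, removed_cell_ids = ct$cell_ids[empty])
}

#' Read a cell-metadata table
#'
#' Tab-separated file with columns `cell_id`, `subset` and optionally
#' `batch`. Subset labels must be classical / intermediate / non_classical.
#'
#' @param path file path.
#' @return data.frame with columns `cell_id`, `subset` (factor), `batch`.
#' @export
read_cell_meta <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  .assert(all(c("cell_id", "subset") %in% colnames(df)),
          "metadata needs columns cell_id and subset")
  cell_meta(df$cell_id, df$subset, df$batch %||% NULL)
}

#' Construct cell metadata
#'
#' @param cell_id character vector of unique cell identifiers.
#' @param subset subset label per cell (classical / intermediate /
#'   non_classical).
#' @param batch optional plate or chip identifier per cell.
#' @return data.frame with one row per cell.
#' @export
cell_meta <- function(cell_id, subset, batch = NULL) {
  cell_id <- as.character(cell_id)
  .assert(!anyDuplicated(cell_id), "duplicate cell_id in metadata")
  .assert(length(subset) == length(cell_id), "subset length mismatch")
  df <- data.frame(cell_id = cell_id, subset = .check_subsets(subset),
                   stringsAsFactors = FALSE)
  df$batch <- if (is.null(batch)) "batch1" else as.character(batch)
  df
}

#' Align cell metadata to a Ct table
#'
#' Matches every cell of `ct` to exactly one metadata row. In strict mode
#' (default) a cell missing from the metadata is an error; otherwise the
#' unmatched cells are dropped from the returned annotation and reported via
#' the `"unmatched"` attribute.
#'
#' @param ct [ct_table()]
#' @param meta data.frame as from [cell_meta()].
#' @param strict error on unmatched cells?
#' @return metadata data.frame reordered to `ct$cell_ids` (strict) or to the
#'   matched subset of them, with attribute `"unmatched"`.
#' @export
join_metadata <- function(ct, meta, strict = TRUE) {
  .assert(inherits(ct, "ct_table"), "ct must be a ct_table")
  .assert(!anyDuplicated(meta$cell_id), "duplicate metadata row for a cell")
  idx <- match(ct$cell_ids, meta$cell_id)
  unmatched <- ct$cell_ids[is.na(idx)]
  if (strict) .assert(length(unmatched) == 0L,
                      "cells missing from metadata: ",
                      paste(utils::head(unmatched, 5L), collapse = ", "))
  out <- meta[idx[!is.na(idx)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  out
}
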