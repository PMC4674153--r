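#' Normalization configuration
#'
#' Settings for the Ct-to-expression transform and optional normalization.
#'
#' `lod_ct` anchors the limit-of-detection transform
#' `Log2Ex = max(0, lod_ct - Ct)`: a reaction at the detection ceiling maps
#' to 0, and every cycle below the ceiling doubles the estimated abundance,
#' i.e. adds one log2 unit. The default of 24 cycles is the common BioMark
#' convention after pre-amplification. All downstream statistics (dip test,
#' t contrasts, fold changes, PCA up to a location shift) are invariant to
#' `lod_ct` up to an additive shift of the detected values.
#'
#' Modes:
#' \describe{
#'   \item{none}{identity (default). Subset-level summaries remain on the raw
#'     Log2Ex scale.}
#'   \item{per_cell_delta}{classic per-cell delta-Ct: the reference gene's
#'     value is subtracted from every gene of that cell and the result is
#'     clamped at 0, so the reference becomes exactly 0 everywhere. Cells in
#'     which the reference itself is undetected cannot be normalized this way
#'     and are dropped (reported via the `"excluded_cells"` attribute).}
#'   \item{global_scale}{batch-level location adjustment: every batch is
#'     shifted by a constant so that its median reference value equals the
#'     global median reference value. Differences between genes within a cell
#'     are preserved exactly; with a single batch this is the identity.}
#' }
#'
#' @param lod_ct detection ceiling in cycles (> 0).
#' @param mode one of `"none"`, `"per_cell_delta"`, `"global_scale"`.
#' @param reference_gene housekeeping assay used by the non-trivial modes.
#' @return list of class `norm_config`.
#' @export
norm_config <- function(lod_ct = 24,
                        mode = c("none", "per_cell_delta", "global_scale"),
                        reference_gene = "ACTB") {
  mode <- match.arg(mode)
  .assert(is.numeric(lod_ct) && length(lod_ct) == 1L && lod_ct > 0,
          "lod_ct must be a single value > 0")
  structure(list(lod_ct = lod_ct, mode = mode,
                 reference_gene = reference_gene),
            class = "norm_config")
}

#' Convert Ct values to Log2Ex expression
#'
#' `Log2Ex = max(0, lod_ct - Ct)` for detected reactions; nondetects map to
#' 0. A value of 0 therefore means "at or below the detection limit"
#' (non-expression); the transform never produces negative values and is
#' antitone in Ct.
#'
#' @param ct [ct_table()], normally after [filter_empty_wells()].
#' @param cfg [norm_config()]
#' @return numeric matrix (cells x genes) of nonnegative Log2Ex values.
#' @export
ct_to_log2ex <- function(ct, cfg = norm_config()) {
  .assert(inherits(ct, "ct_table"), "ct must be a ct_table")
  x <- cfg$lod_ct - ct$ct
  x[x < 0 | is.na(x)] <- 0
  x
}

#' Normalize a Log2Ex matrix
#'
#' See [norm_config()] for the semantics of each mode.
#'
#' @param expr cells x genes Log2Ex matrix.
#' @param cfg [norm_config()]
#' @param meta optional cell metadata (needed for batch assignment under
#'   `global_scale`; single batch assumed when absent).
#' @return normalized matrix; under `per_cell_delta` possibly with fewer
#'   rows and an `"excluded_cells"` attribute.
#' @export
normalize_expression <- function(expr, cfg = norm_config(), meta = NULL) {
  expr <- as.matrix(expr)
  if (cfg$mode == "none") return(expr)
  ref <- cfg$reference_gene
  .assert(ref %in% colnames(expr), "reference gene '", ref, "' not present")
  if (cfg$mode == "per_cell_delta") {
    refv <- expr[, ref]
    # an all-zero reference column (e.g. after a previous delta pass) cannot
    # recalibrate anything: identity, which also makes the mode idempotent
    if (all(refv <= 0)) return(expr)
    bad <- refv <= 0
    if (any(bad))
      message(sum(bad), " cell(s) dropped: reference gene undetected")
    out <- expr[!bad, , drop = FALSE] - refv[!bad]
    out[out < 0] <- 0
    attr(out, "excluded_cells") <- rownames(expr)[bad]
    out
  } else {  # global_scale
    batch <- if (is.null(meta)) rep("batch1", nrow(expr))
             else meta$batch[match(rownames(expr), meta$cell_id)]
    gmed <- stats::median(expr[, ref])
    out <- expr
    for (b in unique(batch)) {
      i <- which(batch == b)
      out[i, ] <- expr[i, , drop = FALSE] +
        (gmed - stats::median(expr[i, ref]))
    }
    out
  }
}

#' Per-gene, per-subset mean expression
#'
#' Arithmetic mean of Log2Ex over all cells of each subset, zeros included
#' (a gene undetected in every cell of a subset therefore has mean exactly
#' 0, the "not expressed" convention used by the presence filters in
#' [never_expressed()] and friends).
#'
#' @param expr cells x genes Log2Ex matrix.
#' @param meta cell metadata covering every row of `expr`.
#' @return data.frame with columns `gene`, `classical`, `intermediate`,
#'   `non_classical`, ordered by gene as in `expr`.
#' @export
subset_mean_table <- function(expr, meta) {
  expr <- as.matrix(expr)
  sub <- .check_subsets(meta$subset[match(rownames(expr), meta$cell_id)])
  .assert(!anyNA(sub), "every cell must have a subset label")
  .assert(all(table(sub) > 0L), "empty subset: ",
          paste(SUBSET_LEVELS[table(sub) == 0L], collapse = ", "))
  m <- vapply(SUBSET_LEVELS,
              function(s) colMeans(expr[sub == s, , drop = FALSE]),
              numeric(ncol(expr)))
  out <- data.frame(gene = colnames(expr), m, row.names = NULL,
                    check.names = FALSE)
  colnames(out) <- c("gene", SUBSET_LEVELS)
  out
}
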