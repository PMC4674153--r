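#' Per-gene generative specification
#'
#' Describes how one gene's true Log2Ex is drawn within each subset:
#' `Normal(mu_s, sd^2)` for unimodal genes; for bimodal genes a draw from
#' `Normal(mu1, sd^2)` with probability `1 - pi` and from
#' `Normal(mu2, sd^2)` with probability `pi`, shifted per subset so the
#' mixture mean tracks `mu_s`. Draws are clamped at 0 (the detection
#' floor).
#'
#' @param gene_id gene name.
#' @param mu per-subset mean Log2Ex: a single number or a length-3 vector
#'   named with the subset levels.
#' @param sd within-component standard deviation (log2 units, > 0).
#' @param modality `"unimodal"` or `"bimodal"`.
#' @param mu1,mu2 component means for bimodal genes (`mu1 < mu2`); the
#'   per-subset `mu` then acts as an additive location offset relative to
#'   the mixture mean.
#' @param pi upper-component weight in `(0, 1)` for bimodal genes.
#' @return list of class `gene_spec`.
#' @export
gene_spec <- function(gene_id, mu, sd = 1.5,
                      modality = c("unimodal", "bimodal"),
                      mu1 = NULL, mu2 = NULL, pi = 0.5) {
  modality <- match.arg(modality)
  .assert(sd > 0, "sd must be > 0")
  if (length(mu) == 1L) mu <- stats::setNames(rep(mu, 3L), SUBSET_LEVELS)
  .assert(all(SUBSET_LEVELS %in% names(mu)), "mu must cover the three subsets")
  if (modality == "bimodal") {
    .assert(!is.null(mu1) && !is.null(mu2) && mu1 < mu2, "need mu1 < mu2")
    .assert(pi > 0 && pi < 1, "pi must be in (0, 1)")
  }
  structure(list(gene_id = gene_id, mu = mu[SUBSET_LEVELS], sd = sd,
                 modality = modality, mu1 = mu1, mu2 = mu2, pi = pi),
            class = "gene_spec")
}

#' Gene specifications seeded from a subset-mean table
#'
#' One unimodal [gene_spec()] per row, with the table's per-subset means as
#' `mu_s`.
#'
#' @param means subset-mean table (e.g. [monocyte_subset_means()]).
#' @param sd common within-gene standard deviation.
#' @return list of `gene_spec`.
#' @export
gene_specs_from_means <- function(means = monocyte_subset_means(), sd = 1.5) {
  lapply(seq_len(nrow(means)), function(i)
    gene_spec(means$gene[i],
              stats::setNames(as.numeric(means[i, SUBSET_LEVELS]),
                              SUBSET_LEVELS),
              sd = sd))
}

#' Simulation configuration
#'
#' Study conditions of a synthetic single-cell qPCR experiment. The
#' defaults mirror the reference monocyte data set: 94 / 92 / 90 cells in
#' the classical / intermediate / non-classical subsets and the bundled
#' 85-gene panel means. Dropout is logistic in the true expression:
#' `P(nondetect | x) = 1 / (1 + exp(s * (x - m0)))`, decreasing in `x`, so
#' weakly expressed transcripts are the ones lost. Detected values are
#' emitted as `Ct = lod_ct - x + Normal(0, ct_noise_sd^2)`; empty wells are
#' created by pushing the 18S control past the 40-cycle ceiling.
#'
#' @param n_cells length-3 vector of per-subset cell counts.
#' @param genes list of [gene_spec()].
#' @param lod_ct detection ceiling (cycles).
#' @param ct_noise_sd measurement noise of detected Ct values (cycles).
#' @param empty_well_rate probability a well receives no cell.
#' @param dropout_midpoint `m0` of the logistic dropout (Log2Ex units);
#'   `-Inf` disables dropout.
#' @param dropout_slope `s` of the logistic dropout (per Log2Ex unit).
#' @param subgroup optional planted subgroup: list with `subset`,
#'   `fraction`, `genes` (affected gene ids) and `shift` (log2 units added
#'   for member cells).
#' @param seed integer seed; the whole experiment is reproducible from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cells = c(classical = 94, intermediate = 92,
                                   non_classical = 90),
                       genes = gene_specs_from_means(),
                       lod_ct = 24, ct_noise_sd = 0.5,
                       empty_well_rate = 0.02,
                       dropout_midpoint = 3, dropout_slope = 1.5,
                       subgroup = NULL, seed = 1) {
  .assert(length(n_cells) == 3L && all(n_cells > 0), "need 3 positive counts")
  if (is.null(names(n_cells))) names(n_cells) <- SUBSET_LEVELS
  .assert(empty_well_rate >= 0 && empty_well_rate <= 1, "bad empty_well_rate")
  .assert(ct_noise_sd >= 0, "bad ct_noise_sd")
  if (!is.null(subgroup)) {
    .assert(subgroup$subset %in% SUBSET_LEVELS, "bad subgroup subset")
    .assert(subgroup$fraction > 0 && subgroup$fraction < 0.5,
            "subgroup fraction must be in (0, 0.5)")
  }
  structure(list(n_cells = n_cells[SUBSET_LEVELS], genes = genes,
                 lod_ct = lod_ct, ct_noise_sd = ct_noise_sd,
                 empty_well_rate = empty_well_rate,
                 dropout_midpoint = dropout_midpoint,
                 dropout_slope = dropout_slope,
                 subgroup = subgroup, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a single-cell qPCR experiment
#'
#' Draws true Log2Ex per cell and gene from the configured per-gene model
#' (plus the planted subgroup shift where configured), clamps at 0, applies
#' logistic dropout, emits detected values as noisy Ct, appends an 18S
#' occupancy control (empty wells get an 18S Ct above the ceiling and no
#' target signal at all), and returns the raw table together with the
#' ground truth needed for recovery scoring.
#'
#' @param cfg [sim_config()]
#' @return list with `ct` ([ct_table()] including the 18S column), `meta`
#'   (cell metadata) and `truth` (list: `log2ex` true-value matrix,
#'   `dropout` logical matrix, `cells` per-cell data.frame with subgroup
#'   membership, `genes` per-gene modality table, `empty_wells`).
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  with_seed(cfg$seed, .simulate_experiment(cfg))
}

.simulate_experiment <- function(cfg) {
  genes <- vapply(cfg$genes, function(g) g$gene_id, "")
  .assert(!anyDuplicated(genes), "duplicate gene ids in config")
  subsets <- rep(SUBSET_LEVELS, times = cfg$n_cells)
  n <- length(subsets)
  cells <- sprintf("cell%03d", seq_len(n))
  meta <- cell_meta(cells, subsets)

  in_sub <- rep(FALSE, n)
  if (!is.null(cfg$subgroup)) {
    idx <- which(subsets == cfg$subgroup$subset)
    k <- max(1L, round(cfg$subgroup$fraction * length(idx)))
    in_sub[sample(idx, k)] <- TRUE
  }

  true_x <- matrix(0, n, length(genes), dimnames = list(cells, genes))
  for (j in seq_along(cfg$genes)) {
    g <- cfg$genes[[j]]
    mu_s <- g$mu[subsets]
    if (g$modality == "unimodal") {
      x <- stats::rnorm(n, mu_s, g$sd)
    } else {
      up <- stats::runif(n) < g$pi
      mix_mean <- (1 - g$pi) * g$mu1 + g$pi * g$mu2
      x <- stats::rnorm(n, ifelse(up, g$mu2, g$mu1), g$sd) + (mu_s - mix_mean)
    }
    if (!is.null(cfg$subgroup) && g$gene_id %in% cfg$subgroup$genes)
      x[in_sub] <- x[in_sub] + cfg$subgroup$shift
    true_x[, j] <- pmax(0, x)
  }

  p_drop <- 1 / (1 + exp(cfg$dropout_slope * (true_x - cfg$dropout_midpoint)))
  if (identical(cfg$dropout_midpoint, -Inf)) p_drop[] <- 0
  drop <- matrix(stats::runif(length(p_drop)) < p_drop, n,
                 dimnames = dimnames(true_x))

  ct <- cfg$lod_ct - true_x +
    matrix(stats::rnorm(length(true_x), 0, cfg$ct_noise_sd), n)
  ct[drop] <- NA
  ct[!is.na(ct) & ct <= 0] <- 0.01   # guard: Ct must stay positive

  empty <- stats::runif(n) < cfg$empty_well_rate
  ctrl <- stats::rnorm(n, 12, 0.5)
  ctrl[empty] <- stats::runif(sum(empty), 41, 45)
  ct[empty, ] <- NA                  # an empty well has no target signal

  ct_full <- cbind(ct, `18S` = ctrl)
  truth_genes <- data.frame(
    gene = genes,
    modality = vapply(cfg$genes, function(g) g$modality, ""),
    sd = vapply(cfg$genes, function(g) g$sd, 0))
  list(ct = ct_table(ct_full, cells, c(genes, "18S")),
       meta = meta,
       truth = list(log2ex = true_x, dropout = drop,
                    cells = data.frame(cell_id = cells, subset = subsets,
                                       in_subgroup = in_sub),
                    genes = truth_genes,
                    empty_wells = cells[empty]))
}

#' Score recovery of simulated ground truth
#'
#' Compares pipeline output against a simulation's truth: confusion of the
#' modality screen (sensitivity = flagged fraction of truly bimodal
#' strata, specificity = unflagged fraction of truly unimodal strata),
#' adjusted Rand index between recovered subgroup membership and the
#' planted one within the affected subset, and precision/recall of the
#' subgroup DE gene list against the planted genes.
#'
#' @param truth `truth` element of [simulate_experiment()].
#' @param dip_results optional output of [screen_modality()].
#' @param subgroup optional recovered subgroup (list with `members`), as
#'   from [select_subgroup()]/[find_subgroups()]; an absent/NULL subgroup
#'   scores ARI 0 when a subgroup was planted.
#' @param de optional DE table as from [subgroup_de()].
#' @param planted optional planted-subgroup description
#'   (`sim_config()$subgroup`); needed for ARI and DE scoring.
#' @return list of metrics (elements NULL where inputs were not given).
#' @export
evaluate_recovery <- function(truth, dip_results = NULL, subgroup = NULL,
                              de = NULL, planted = NULL) {
  out <- list()
  if (!is.null(dip_results)) {
    cls <- truth$genes$modality[match(dip_results$gene, truth$genes$gene)]
    flagged <- dip_results$multimodal %in% TRUE
    out$modality_sensitivity <- if (any(cls == "bimodal"))
      mean(flagged[cls == "bimodal"]) else NULL
    out$modality_specificity <- if (any(cls == "unimodal"))
      mean(!flagged[cls == "unimodal"]) else NULL
  }
  if (!is.null(planted)) {
    cells <- truth$cells[truth$cells$subset == planted$subset, ]
    pred <- cells$cell_id %in% (subgroup$members %||% character(0))
    out$subgroup_ari <- .adjusted_rand(cells$in_subgroup, pred)
    if (!is.null(de)) {
      hits <- de$gene
      out$de_precision <- if (length(hits)) mean(hits %in% planted$genes) else 0
      out$de_recall <- mean(planted$genes %in% hits)
    }
  }
  out
}

.adjusted_rand <- function(a, b) {
  if (length(unique(a)) == 1L && length(unique(b)) == 1L) return(1)
  mclust::adjustedRandIndex(a, b)
}
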