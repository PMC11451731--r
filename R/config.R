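#' Pipeline configuration
#'
#' Bundles every tuning constant of the metaprogram discovery pipeline in one
#' validated object. Defaults follow the published procedure: genes kept when
#' detected in at least 1% of malignant cells, 30 NMF factors per cohort,
#' loading z-score threshold 1.5, Spearman co-expression edges above 0.4,
#' factors discarded below 10 prioritized genes, AUCell-style scoring over the
#' top 5% of ranks, consensus genes present in at least 25% of member factors,
#' metaprograms discarded when active in fewer than 10% of cells, 100
#' stability repeats scored by 5-fold cross-validated auROC, a k=30
#' Mahalanobis kNN graph with Louvain resolution 0.4 and 100 consensus runs,
#' and a cross-cohort correlation floor of 0.2 tested at alpha 0.05.
#'
#' @param min_gene_cell_frac fraction of pooled malignant cells in which a
#'   gene must be detected to be kept.
#' @param n_factors NMF rank per cohort.
#' @param loading_z_threshold z-score (per gene, across factors) above which a
#'   gene is a candidate for a factor.
#' @param coexpr_corr_threshold Spearman correlation above which two candidate
#'   genes are joined in the co-expression graph.
#' @param min_prioritized_genes factors with fewer prioritized genes are
#'   discarded.
#' @param auc_top_frac fraction of top-ranked genes over which the recovery
#'   AUC is integrated.
#' @param consensus_gene_frac minimum fraction of member factors a gene must
#'   appear in to enter a metaprogram's consensus list.
#' @param min_active_cell_frac metaprograms active in fewer than this fraction
#'   of cells in every cohort are discarded.
#' @param inactive_rule `"all"` discards a metaprogram only when inactive in
#'   all cohorts (default); `"any"` discards when inactive in any cohort.
#' @param n_stability_runs number of independent discovery repeats.
#' @param cv_folds folds for the stability classifier.
#' @param knn_k neighbors for the cell-state graph.
#' @param louvain_resolution resolution of the Louvain modularity.
#' @param n_louvain_runs consensus Louvain repeats.
#' @param min_cells_per_tumor tumors with fewer cells are skipped in
#'   tumor-wise correlation.
#' @param cross_cohort_corr_floor correlation floor for the one-sided
#'   Wilcoxon test of cross-cohort metaprogram correspondence.
#' @param alpha significance level.
#' @param master_seed integer; every random stage derives its seed from this.
#'
#' @return An object of class `mp_config` (a validated named list).
#' @examples
#' cfg <- mp_config(n_stability_runs = 5, master_seed = 7)
#' cfg$n_factors
#' @export
mp_config <- function(min_gene_cell_frac = 0.01,
                      n_factors = 30L,
                      loading_z_threshold = 1.5,
                      coexpr_corr_threshold = 0.4,
                      min_prioritized_genes = 10L,
                      auc_top_frac = 0.05,
                      consensus_gene_frac = 0.25,
                      min_active_cell_frac = 0.10,
                      inactive_rule = c("all", "any"),
                      n_stability_runs = 100L,
                      cv_folds = 5L,
                      knn_k = 30L,
                      louvain_resolution = 0.4,
                      n_louvain_runs = 100L,
                      min_cells_per_tumor = 20L,
                      cross_cohort_corr_floor = 0.2,
                      alpha = 0.05,
                      master_seed = 1L) {
  inactive_rule <- match.arg(inactive_rule)
  cfg <- list(
    min_gene_cell_frac = as.numeric(min_gene_cell_frac),
    n_factors = as.integer(n_factors),
    loading_z_threshold = as.numeric(loading_z_threshold),
    coexpr_corr_threshold = as.numeric(coexpr_corr_threshold),
    min_prioritized_genes = as.integer(min_prioritized_genes),
    auc_top_frac = as.numeric(auc_top_frac),
    consensus_gene_frac = as.numeric(consensus_gene_frac),
    min_active_cell_frac = as.numeric(min_active_cell_frac),
    inactive_rule = inactive_rule,
    n_stability_runs = as.integer(n_stability_runs),
    cv_folds = as.integer(cv_folds),
    knn_k = as.integer(knn_k),
    louvain_resolution = as.numeric(louvain_resolution),
    n_louvain_runs = as.integer(n_louvain_runs),
    min_cells_per_tumor = as.integer(min_cells_per_tumor),
    cross_cohort_corr_floor = as.numeric(cross_cohort_corr_floor),
    alpha = as.numeric(alpha),
    master_seed = as.integer(master_seed)
  )
  validate_mp_config(cfg)
  structure(cfg, class = "mp_config")
}

validate_mp_config <- function(cfg) {
  fracs <- c("min_gene_cell_frac", "auc_top_frac", "consensus_gene_frac",
             "min_active_cell_frac", "alpha")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.finite(v) || v <= 0 || v >= 1) {
      stop(sprintf("config field '%s' must be a fraction in (0,1), got %s",
                   f, format(v)), call. = FALSE)
    }
  }
  counts <- c("n_factors", "min_prioritized_genes", "n_stability_runs",
              "cv_folds", "knn_k", "n_louvain_runs", "min_cells_per_tumor")
  for (f in counts) {
    v <- cfg[[f]]
    if (is.na(v) || v < 1L) {
      stop(sprintf("config field '%s' must be a count >= 1", f), call. = FALSE)
    }
  }
  thr <- c("loading_z_threshold", "coexpr_corr_threshold",
           "louvain_resolution", "cross_cohort_corr_floor")
  for (f in thr) {
    if (!is.finite(cfg[[f]])) {
      stop(sprintf("config field '%s' must be finite", f), call. = FALSE)
    }
  }
  if (is.na(cfg$master_seed)) stop("master_seed must be an integer", call. = FALSE)
  invisible(cfg)
}

#' @export
print.mp_config <- function(x, ...) {
  cat("Metaprogram pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a pipeline configuration as JSON
#'
#' @param path file path.
#' @return `read_config()` returns an `mp_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(mp_config, vals)
}

#' @rdname read_config
#' @param config an `mp_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "mp_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Deterministic per-stage seed derivation. Every stochastic stage calls this
# with a stage name and a run index so that 100 "parallel" repeats are
# reproducible and order-independent. Polynomial string hash mod a prime below
# 2^31; arithmetic stays in double precision well under 2^53.
#' Derive a stage seed from the master seed
#'
#' @param master_seed integer master seed.
#' @param stage character scalar naming the stage.
#' @param index run index (0 for singleton stages).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master_seed, stage, index = 0L) {
  m <- 2147483587  # prime < 2^31
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer((h + (as.numeric(master_seed) %% m) * 7919 +
                as.numeric(index) * 104729) %% m)
}
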