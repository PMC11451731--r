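#' Pearson correlation between factor activities
#'
#' Symmetric unit-diagonal Pearson correlation matrix of per-cell factor
#' activity scores over the pooled cells of all cohorts. Constant-score
#' factors get correlation 0 against all others and are flagged in the
#' `"constant"` attribute.
#'
#' @param activities an `activity_matrix` whose columns are factor scores.
#' @return A factors x factors correlation matrix.
#' @export
factor_activity_correlation <- function(activities) {
  stopifnot(inherits(activities, "activity_matrix"))
  sc <- activities$scores
  sdv <- apply(sc, 2, stats::sd)
  const <- !is.finite(sdv) | sdv == 0
  cc <- suppressWarnings(stats::cor(sc))
  cc[const, ] <- 0
  cc[, const] <- 0
  diag(cc) <- 1
  attr(cc, "constant") <- colnames(sc)[const]
  cc
}

#' Cluster factors into metaprograms by silhouette-selected hierarchical cuts
#'
#' Agglomerative (average linkage) clustering on distance `1 - correlation`;
#' for each candidate number of clusters the mean silhouette width (same
#' distance) is computed, and the k maximizing it is chosen (ties to the
#' smaller k).
#'
#' @param corr factor correlation matrix.
#' @param k_candidates integer vector of candidate cluster counts (clipped to
#'   `[2, n - 1]`).
#' @return A list: `labels` (chosen cut), `chosen_k`, `silhouettes`
#'   (data frame `k`, `mean_silhouette`).
#' @export
cluster_factors <- function(corr, k_candidates = 2:15) {
  n <- nrow(corr)
  off <- corr[upper.tri(corr)]
  if (n >= 3L && length(unique(round(off, 12))) == 1L) {
    stop("all inter-factor correlations are equal; silhouette is undefined, ",
         "choose k manually", call. = FALSE)
  }
  d <- stats::as.dist(pmax(1 - corr, 0))
  hc <- stats::hclust(d, method = "average")
  ks <- sort(unique(as.integer(k_candidates)))
  ks <- ks[ks >= 2L & ks <= n - 1L]
  if (!length(ks)) stop("no feasible k in k_candidates", call. = FALSE)
  sil <- vapply(ks, function(k) {
    lab <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, 0)
  chosen <- ks[which.max(sil)]  # which.max takes the first (smallest) max
  list(labels = stats::cutree(hc, k = chosen), chosen_k = chosen,
       silhouettes = data.frame(k = ks, mean_silhouette = sil))
}

#' Consensus gene list of a metaprogram
#'
#' A gene enters the consensus when it appears in at least
#' `ceil(min_frac * n_member_factors)` of the member factors' prioritized
#' lists (so with the default 25% and 4 members, presence in a single list
#' suffices). Output ordered by occurrence count (descending), then gene id.
#'
#' @param mp_factors list of prioritized gene lists (one per member factor).
#' @param min_frac consensus fraction threshold.
#' @return A character vector (possibly empty).
#' @export
consensus_genes <- function(mp_factors, min_frac = 0.25) {
  stopifnot(length(mp_factors) >= 1L)
  counts <- table(unlist(lapply(mp_factors, unique)))
  need <- ceiling(min_frac * length(mp_factors))
  keep <- counts[counts >= need]
  if (!length(keep)) return(character(0))
  nm <- names(keep)[order(-as.integer(keep), names(keep))]
  nm
}

#' Drop metaprograms inactive in (almost) all cells
#'
#' With the default rule `"all"`, a metaprogram is discarded only when its
#' active-cell fraction is below `min_active_frac` in every cohort — a
#' program active in one model is a reportable model-enriched program. The
#' alternative rule `"any"` discards when inactive in any cohort. Survivors
#' are re-labeled `MP1..MPm` by descending total active fraction.
#'
#' @param mps list of metaprogram records (each with `genes`,
#'   `member_factors`, `active_frac`).
#' @param min_active_frac activity fraction threshold.
#' @param rule `"all"` (default) or `"any"`.
#' @return The surviving, re-labeled list.
#' @export
drop_inactive <- function(mps, min_active_frac = 0.10,
                          rule = c("all", "any")) {
  rule <- match.arg(rule)
  keep <- vapply(mps, function(mp) {
    below <- mp$active_frac < min_active_frac
    if (rule == "all") !all(below) else !any(below)
  }, TRUE)
  mps <- mps[keep]
  if (!length(mps)) return(mps)
  tot <- vapply(mps, function(mp) mp$total_active_frac, 0)
  mps <- mps[order(-tot)]
  for (i in seq_along(mps)) mps[[i]]$id <- sprintf("MP%d", i)
  mps
}

#' Assemble metaprograms from prioritized per-cohort factor sets
#'
#' Scores every retained factor's prioritized genes over the pooled cells,
#' correlates factor activities (Pearson), clusters factors by
#' silhouette-selected hierarchical clustering, forms per-cluster consensus
#' gene lists, scores the resulting metaprograms, and discards those active
#' in fewer than `config$min_active_cell_frac` of cells per the configured
#' rule.
#'
#' @param factor_sets list of prioritized `factor_set`s (one per cohort).
#' @param counts the pooled filtered `count_matrix` (malignant cells of all
#'   cohorts).
#' @param config an `mp_config`.
#' @param seed integer seed for activity tie-breaking.
#' @return A list: `metaprograms` (list of records: `id`, `member_factors`,
#'   `genes`, `active_frac`, `total_active_frac`), `activities`
#'   (`activity_matrix` of the metaprograms), `factor_activities`,
#'   `factor_clustering`.
#' @export
assemble_metaprograms <- function(factor_sets, counts, config,
                                  seed = config$master_seed) {
  stopifnot(inherits(counts, "count_matrix"), inherits(config, "mp_config"))
  sets <- list()
  members <- list()
  for (fs in factor_sets) {
    keep <- which(fs$retained)
    for (j in keep) {
      nm <- sprintf("%s.F%d", fs$cohort, j)
      sets[[nm]] <- fs$prioritized_genes[[j]]
      members[[nm]] <- list(cohort = fs$cohort, factor = j)
    }
  }
  if (!length(sets)) {
    return(list(metaprograms = list(), activities = NULL,
                factor_activities = NULL, factor_clustering = NULL))
  }
  fact_act <- score_programs(counts, gene_set_collection(sets),
                             top_frac = config$auc_top_frac,
                             seed = derive_seed(seed, "factor_activity"))
  if (length(sets) < 3L) {
    labels <- stats::setNames(seq_along(sets), names(sets))
    clust <- list(labels = labels, chosen_k = length(sets),
                  silhouettes = NULL)
  } else {
    corr <- factor_activity_correlation(fact_act)
    kmax <- min(15L, length(sets) - 1L)
    clust <- cluster_factors(corr, 2:kmax)
  }
  cohorts <- unique(counts$cohort)
  mps <- list()
  for (cl in sort(unique(clust$labels))) {
    nms <- names(clust$labels)[clust$labels == cl]
    genes <- consensus_genes(sets[nms], config$consensus_gene_frac)
    if (!length(genes)) {
      warning("empty consensus gene list; metaprogram dropped", call. = FALSE)
      next
    }
    mps[[length(mps) + 1L]] <- list(
      id = sprintf("cluster%d", cl),
      member_factors = members[nms],
      genes = genes)
  }
  if (!length(mps)) {
    return(list(metaprograms = list(), activities = NULL,
                factor_activities = fact_act, factor_clustering = clust))
  }
  mp_sets <- gene_set_collection(
    stats::setNames(lapply(mps, `[[`, "genes"),
                    sprintf("tmp%d", seq_along(mps))))
  mp_act <- score_programs(counts, mp_sets, top_frac = config$auc_top_frac,
                           seed = derive_seed(seed, "mp_activity"))
  for (i in seq_along(mps)) {
    act <- mp_act$active[, i]
    mps[[i]]$active_frac <- vapply(cohorts, function(ch) {
      mean(act[counts$cohort == ch])
    }, 0)
    mps[[i]]$total_active_frac <- mean(act)
  }
  mps <- drop_inactive(mps, config$min_active_cell_frac,
                       rule = config$inactive_rule)
  if (!length(mps)) {
    return(list(metaprograms = list(), activities = NULL,
                factor_activities = fact_act, factor_clustering = clust))
  }
  final_sets <- gene_set_collection(
    stats::setNames(lapply(mps, `[[`, "genes"),
                    vapply(mps, `[[`, "", "id")))
  final_act <- score_programs(counts, final_sets,
                              top_frac = config$auc_top_frac,
                              seed = derive_seed(seed, "mp_activity"))
  list(metaprograms = mps, activities = final_act,
       factor_activities = fact_act, factor_clustering = clust)
}

#' Export metaprograms as a gene set collection
#' @param mps metaprogram list as returned in `assemble_metaprograms()$metaprograms`.
#' @return A `gene_set_collection` named by metaprogram id.
#' @export
metaprogram_gene_sets <- function(mps) {
  gene_set_collection(stats::setNames(lapply(mps, `[[`, "genes"),
                                      vapply(mps, `[[`, "", "id")))
}
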