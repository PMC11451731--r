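#' Filter genes by detection fraction
#'
#' Keeps genes detected (nonzero count) in at least
#' `ceil(min_frac * n_cells)` of the pooled cells, so with the default 1%
#' threshold a gene seen in exactly 1 of 100 cells is kept. Gene order is
#' preserved. The caller is expected to restrict to malignant cells first.
#'
#' @param counts a `count_matrix`, cells pooled across cohorts.
#' @param min_frac detection fraction threshold.
#' @return The filtered `count_matrix`.
#' @export
filter_genes <- function(counts, min_frac) {
  stopifnot(inherits(counts, "count_matrix"), min_frac >= 0)
  n <- ncol(counts$counts)
  ncell <- Matrix::rowSums(counts$counts > 0)
  keep <- ncell >= ceiling(min_frac * n)
  if (!any(keep)) stop("no genes survive the detection filter", call. = FALSE)
  subset_cells(counts, genes = which(keep))
}

#' Per-cohort NMF decomposition
#'
#' Runs unregularized NMF (HALS, Frobenius objective) on the log1p
#' counts-per-10k matrix of one cohort's cells, from a seeded random
#' non-negative initialization. Converges when the relative change of the
#' relative reconstruction error falls below `tol`, or after `max_iter`
#' sweeps.
#'
#' @param counts a filtered `count_matrix`.
#' @param cohort cohort label to factorize (must exist in `counts$cohort`).
#' @param n_factors rank of the factorization.
#' @param seed integer seed for the initialization.
#' @param tol,max_iter convergence controls.
#' @return An object of class `factor_set`: `loadings` (genes x factors),
#'   `cell_weights` (factors x cells), `cohort`, `seed`, `rel_error`,
#'   `iterations`; `prioritized_genes` and `retained` are filled in by
#'   [prioritize_factor_genes()].
#' @export
run_nmf <- function(counts, cohort, n_factors, seed, tol = 1e-5,
                    max_iter = 500L) {
  stopifnot(inherits(counts, "count_matrix"))
  sel <- counts$cohort == cohort
  if (!any(sel)) stop("cohort not present: ", cohort, call. = FALSE)
  sub <- subset_cells(counts, cells = sel)
  A <- normalize_log_cp10k(sub)
  if (n_factors > min(dim(A))) {
    stop(sprintf("n_factors (%d) exceeds min(genes, cells) = %d",
                 n_factors, min(dim(A))), call. = FALSE)
  }
  set.seed(seed)
  k <- as.integer(n_factors)
  scale0 <- sqrt(mean(A) / k)
  W0 <- matrix(stats::runif(nrow(A) * k), nrow(A), k) * scale0
  H0 <- matrix(stats::runif(k * ncol(A)), k, ncol(A)) * scale0
  fit <- nmf_hals(A, W0, H0, as.integer(max_iter), tol)
  W <- fit$W
  H <- fit$H
  dimnames(W) <- list(rownames(A), sprintf("F%d", seq_len(k)))
  dimnames(H) <- list(sprintf("F%d", seq_len(k)), colnames(A))
  structure(list(cohort = cohort, loadings = W, cell_weights = H,
                 prioritized_genes = NULL, retained = NULL,
                 seed = as.integer(seed), rel_error = fit$rel_error,
                 iterations = fit$iterations),
            class = "factor_set")
}

#' @export
print.factor_set <- function(x, ...) {
  cat(sprintf("factor_set [%s]: %d genes x %d factors (rel. error %.4g)\n",
              x$cohort, nrow(x$loadings), ncol(x$loadings), x$rel_error))
  if (!is.null(x$retained)) {
    cat(sprintf("  retained factors: %d of %d\n", sum(x$retained),
                length(x$retained)))
  }
  invisible(x)
}

#' Reconstruction error across candidate ranks
#'
#' Runs the factorization at each rank (shared seed) and reports the relative
#' Frobenius reconstruction error, for caller-side elbow inspection; no
#' automatic rank selection is performed.
#'
#' @inheritParams run_nmf
#' @param ranks integer vector of candidate ranks, ascending.
#' @return A data frame with columns `rank` and `rel_error`.
#' @export
elbow_rank_scan <- function(counts, cohort, ranks, seed, tol = 1e-5,
                            max_iter = 500L) {
  stopifnot(!is.unsorted(ranks))
  err <- vapply(ranks, function(k) {
    run_nmf(counts, cohort, k, seed, tol, max_iter)$rel_error
  }, 0)
  data.frame(rank = as.integer(ranks), rel_error = err)
}

# z-score each gene's loadings across the factor axis; constant rows get all
# zeros (no candidate anywhere).
zscore_loadings <- function(W) {
  mu <- rowMeans(W)
  sdv <- apply(W, 1, stats::sd)
  z <- (W - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

# Spearman correlation matrix of genes (rows of `expr`) across cells.
spearman_gene_corr <- function(expr) {
  r <- t(apply(expr, 1, rank))
  stats::cor(t(r))
}

#' Prioritize genes for each factor
#'
#' Two-step rule: (1) per gene, z-score its loading across all factors and
#' keep genes with z above `z_thr` as the factor's candidates; (2) build a
#' co-expression graph on the candidates with edges where the Spearman
#' correlation of expression across the cohort's cells exceeds `corr_thr`,
#' and keep only genes in the largest connected component (component-size
#' ties broken by summed loading, then lexicographic gene order). Factors
#' with fewer than `min_genes` prioritized genes are flagged not retained.
#'
#' @param factors a `factor_set` from [run_nmf()].
#' @param expr the same filtered `count_matrix` the factorization used.
#' @param z_thr loading z-score threshold.
#' @param corr_thr Spearman correlation threshold for graph edges.
#' @param min_genes minimum prioritized genes for a factor to be retained.
#' @return The `factor_set` with `prioritized_genes` (per-factor list,
#'   ordered by decreasing loading) and `retained` filled in.
#' @export
prioritize_factor_genes <- function(factors, expr, z_thr = 1.5,
                                    corr_thr = 0.4, min_genes = 10L) {
  stopifnot(inherits(factors, "factor_set"), inherits(expr, "count_matrix"))
  W <- factors$loadings
  sel <- expr$cohort == factors$cohort
  emat <- normalize_log_cp10k(subset_cells(expr, cells = sel))
  emat <- emat[rownames(W), , drop = FALSE]
  z <- zscore_loadings(W)
  k <- ncol(W)
  prog <- vector("list", k)
  names(prog) <- colnames(W)
  for (j in seq_len(k)) {
    cand <- rownames(W)[z[, j] > z_thr]
    if (length(cand) < 2L) {
      prog[[j]] <- character(0)
      next
    }
    cmat <- spearman_gene_corr(emat[cand, , drop = FALSE])
    comp <- largest_corr_component(cmat, corr_thr, W[cand, j])
    genes <- cand[comp]
    prog[[j]] <- genes[order(-W[genes, j], genes)]
  }
  factors$prioritized_genes <- prog
  factors$retained <- lengths(prog) >= min_genes
  factors
}

# Vertices of the largest connected component of the graph with edges where
# corr > thr. Ties on component size broken by summed loading (descending),
# then by lexicographically smallest sorted vertex-name vector.
largest_corr_component <- function(cmat, thr, loadings) {
  adj <- (cmat > thr)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    load_sums <- vapply(best, function(b) {
      sum(loadings[comp$membership == b])
    }, 0)
    best <- best[order(-load_sums, vapply(best, function(b) {
      paste(sort(rownames(cmat)[comp$membership == b]), collapse = "|")
    }, ""))]
  }
  which(comp$membership == best[[1]])
}

#' Export a factor set's retained gene lists as a collection
#' @param factors a prioritized `factor_set`.
#' @return A `gene_set_collection` with one set per retained factor, named
#'   `<cohort>.F<index>`.
#' @export
factor_gene_sets <- function(factors) {
  stopifnot(inherits(factors, "factor_set"),
            !is.null(factors$prioritized_genes))
  keep <- which(factors$retained)
  if (!length(keep)) {
    stop("no retained factors to export", call. = FALSE)
  }
  sets <- stats::setNames(factors$prioritized_genes[keep],
                          sprintf("%s.F%d", factors$cohort, keep))
  gene_set_collection(sets)
}
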