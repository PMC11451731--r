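#' z-score metaprogram activities across all cells
#'
#' Per metaprogram column: `(x - mean(x)) / sd(x)` over the pooled cells of
#' all cohorts, with the sample (n-1) standard deviation. Zero-variance
#' columns become all zeros with a warning.
#'
#' @param activities an `activity_matrix` or a bare cells x programs matrix.
#' @return A cells x programs numeric matrix.
#' @export
zscore_activities <- function(activities) {
  x <- if (inherits(activities, "activity_matrix")) {
    activities$scores
  } else {
    as.matrix(activities)
  }
  stopifnot(nrow(x) >= 2L)
  sdv <- apply(x, 2, stats::sd)
  z <- sweep(sweep(x, 2, colMeans(x)), 2, ifelse(sdv > 0, sdv, 1), "/")
  if (any(sdv == 0)) {
    warning("zero-variance activity column(s) z-scored to 0", call. = FALSE)
    z[, sdv == 0] <- 0
  }
  z
}

# Mahalanobis-whitened coordinates: rows y_i with ||y_a - y_b|| equal to the
# Mahalanobis distance between rows a, b of z. The covariance is
# ridge-regularized when ill-conditioned (near-collinear metaprograms).
mahalanobis_coords <- function(z) {
  sigma <- stats::cov(z)
  p <- ncol(sigma)
  ok <- tryCatch({chol(sigma); kappa(sigma) <= 1e10}, error = function(e) FALSE)
  if (!ok) {
    sigma <- sigma + diag(1e-6 * sum(diag(sigma)) / p, p)
  }
  R <- tryCatch(chol(sigma), error = function(e)
    stop("covariance singular even after regularization", call. = FALSE))
  # sigma = R'R, d(a,b) = ||R^{-T}(a-b)'|| = ||(a-b) R^{-1}||
  z %*% backsolve(R, diag(p))
}

#' Mahalanobis k-nearest-neighbor graph
#'
#' Distances `sqrt((a-b)' Sigma^{-1} (a-b))` with `Sigma` the sample
#' covariance of the z-scored activities (ridge-regularized when
#' ill-conditioned); each cell is joined to its k nearest others and the
#' union of directed edges is returned as an undirected, unweighted igraph
#' graph. With identity covariance this reduces exactly to the Euclidean kNN
#' graph.
#'
#' @param z cells x programs matrix of z-scored activities.
#' @param k number of neighbors (`k < n`).
#' @return A list: `graph` (igraph), `dist` (the full Mahalanobis `dist`
#'   object, reused for silhouettes).
#' @export
mahalanobis_knn_graph <- function(z, k) {
  n <- nrow(z)
  stopifnot(n > k)
  y <- mahalanobis_coords(z)
  d <- stats::dist(y)
  dm <- as.matrix(d)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- setdiff(order(dm[i, ]), i)[seq_len(k)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- rownames(z)
  list(graph = g, dist = d)
}

#' Consensus Louvain clustering selected by silhouette
#'
#' Runs Louvain modularity optimization (at the given resolution) `n_runs`
#' times with distinct derived seeds, computes the mean silhouette width of
#' each run's labels under the supplied (Mahalanobis) distances, and keeps
#' the run with the highest silhouette (ties to the smaller run index). If
#' every run returns a single cluster the trivial clustering is returned
#' with silhouette `NA`.
#'
#' @param graph an igraph graph (from [mahalanobis_knn_graph()]).
#' @param resolution Louvain resolution parameter.
#' @param n_runs number of consensus repeats.
#' @param distance_matrix a `dist` object for silhouette evaluation.
#' @param seed integer master seed for the repeats.
#' @return A list: `labels` (integer cluster per cell), `silhouette`
#'   (mean width of the kept run, `NA` if undefined), `run_index`.
#' @export
consensus_louvain <- function(graph, resolution = 0.4, n_runs = 100L,
                              distance_matrix, seed = 1L) {
  best <- NULL
  for (r in seq_len(n_runs)) {
    set.seed(derive_seed(seed, "louvain", r))
    cl <- igraph::cluster_louvain(graph, resolution = resolution)
    lab <- igraph::membership(cl)
    sil <- if (length(unique(lab)) >= 2L) {
      mean(cluster::silhouette(as.integer(lab), distance_matrix)[, "sil_width"])
    } else {
      NA_real_
    }
    cand <- list(labels = as.integer(lab), silhouette = sil, run_index = r)
    if (is.null(best) ||
        (!is.na(sil) && (is.na(best$silhouette) || sil > best$silhouette))) {
      best <- cand
    }
  }
  names(best$labels) <- igraph::V(graph)$name
  best
}

#' Cluster malignant cells into states by metaprogram activity
#'
#' z-scores metaprogram activities, builds the Mahalanobis kNN graph, runs
#' consensus Louvain, and (optionally) computes a 2-D UMAP embedding of the
#' z-scored activities for visualization (never used in clustering; requires
#' the `uwot` package).
#'
#' @param activities an `activity_matrix` (e.g. `fit$activities`) or a bare
#'   score matrix.
#' @param k neighbors for the kNN graph.
#' @param resolution Louvain resolution.
#' @param n_runs consensus Louvain repeats.
#' @param seed integer seed.
#' @param embed compute a UMAP embedding?
#' @return An object of class `cell_states`: `labels`, `silhouette`,
#'   `z_activities`, `embedding` (or `NULL`), `mean_z` (clusters x programs
#'   mean z-activity summary).
#' @export
cell_states <- function(activities, k = 30L, resolution = 0.4,
                        n_runs = 100L, seed = 1L, embed = FALSE) {
  z <- zscore_activities(activities)
  kg <- mahalanobis_knn_graph(z, k = min(k, nrow(z) - 1L))
  cl <- consensus_louvain(kg$graph, resolution = resolution, n_runs = n_runs,
                          distance_matrix = kg$dist, seed = seed)
  emb <- if (embed) embed_umap(z, seed = derive_seed(seed, "umap")) else NULL
  mean_z <- do.call(rbind, lapply(sort(unique(cl$labels)), function(g) {
    colMeans(z[cl$labels == g, , drop = FALSE])
  }))
  rownames(mean_z) <- sprintf("T%d", sort(unique(cl$labels)))
  structure(list(labels = cl$labels, silhouette = cl$silhouette,
                 run_index = cl$run_index, z_activities = z,
                 embedding = emb, mean_z = mean_z),
            class = "cell_states")
}

#' @export
print.cell_states <- function(x, ...) {
  cat(sprintf("cell_states: %d cells in %d clusters (silhouette %s)\n",
              length(x$labels), length(unique(x$labels)),
              ifelse(is.na(x$silhouette), "NA",
                     sprintf("%.3f", x$silhouette))))
  print(table(cluster = x$labels))
  invisible(x)
}

#' UMAP embedding of z-scored activities
#'
#' Visualization aid only; deterministic given `seed`. Requires `uwot`.
#'
#' @param z cells x programs matrix (>= 10 cells).
#' @param seed integer seed.
#' @return A cells x 2 coordinate matrix.
#' @export
embed_umap <- function(z, seed = 1L) {
  stopifnot(nrow(z) >= 10L)
  if (!requireNamespace("uwot", quietly = TRUE)) {
    stop("embed_umap requires the 'uwot' package", call. = FALSE)
  }
  set.seed(seed)
  out <- uwot::umap(z, n_neighbors = min(15L, nrow(z) - 1L),
                    n_threads = 1, n_sgd_threads = 0)
  rownames(out) <- rownames(z)
  out
}
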