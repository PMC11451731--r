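#' Discover tumor metaprograms from a two-cohort count matrix
#'
#' The package's central fitting function. Restricts to malignant cells,
#' filters genes by detection fraction, and repeats the discovery procedure
#' (`run_stability()`): per-cohort unregularized NMF on log1p counts-per-10k,
#' gene prioritization by loading z-score and the largest component of a
#' Spearman co-expression graph, AUCell-style activity scoring, factor
#' clustering with silhouette-selected k, consensus gene lists, and
#' inactivity filtering — selecting the repeat whose cohort-separation auROC
#' is the median across repeats.
#'
#' @param counts a `count_matrix` containing malignant cells of exactly two
#'   cohorts (non-malignant cells are dropped).
#' @param config an `mp_config`; `config$master_seed` drives all randomness.
#' @return An object of class `mp_fit` with components `metaprograms`,
#'   `activities` (selected-run `activity_matrix`), `auroc`, `runs`
#'   (stability summary data frame), `all_runs`, `config`, `gene_universe`,
#'   `counts` (the filtered malignant-cell matrix) and `call`. Methods:
#'   `print`, `summary`, `coef` (consensus gene lists), `predict` (score new
#'   cells), `plot` (per-cohort active fractions).
#' @examples
#' \donttest{
#' spec <- synthetic_spec(n_genes = 300, n_cells_per_cohort = 120,
#'                        programs = default_planted_programs(300, 3, 25),
#'                        seed = 7)
#' sim <- generate_mouse_cohorts(spec)
#' cfg <- mp_config(n_factors = 6, n_stability_runs = 2, master_seed = 7)
#' fit <- mp_discover(sim$counts, cfg)
#' print(fit)
#' }
#' @export
mp_discover <- function(counts, config = mp_config()) {
  stopifnot(inherits(counts, "count_matrix"), inherits(config, "mp_config"))
  cl <- match.call()
  mal <- malignant_cells(counts)
  filt <- filter_genes(mal, config$min_gene_cell_frac)
  stab <- run_stability(filt, config)
  sel <- stab$selected
  structure(list(metaprograms = sel$metaprograms,
                 activities = sel$activities,
                 auroc = sel$auroc,
                 selected_run = sel$run_index,
                 runs = stability_summary(stab$runs),
                 all_runs = stab$runs,
                 config = config,
                 gene_universe = filt$gene_ids,
                 counts = filt,
                 call = cl),
            class = "mp_fit")
}

#' @export
print.mp_fit <- function(x, ...) {
  cat("Metaprogram discovery fit\n")
  cat(sprintf("  %d metaprograms from run %d of %d (auROC %.3f)\n",
              length(x$metaprograms), x$selected_run, nrow(x$runs), x$auroc))
  for (mp in x$metaprograms) {
    cat(sprintf("  %-5s %3d genes; active: %s\n", mp$id, length(mp$genes),
                paste(sprintf("%s %.0f%%", names(mp$active_frac),
                              100 * mp$active_frac), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.mp_fit <- function(object, ...) {
  mp_tab <- do.call(rbind, lapply(object$metaprograms, function(mp) {
    data.frame(id = mp$id, n_genes = length(mp$genes),
               n_member_factors = length(mp$member_factors),
               t(mp$active_frac), total_active_frac = mp$total_active_frac)
  }))
  out <- list(metaprograms = mp_tab, runs = object$runs,
              auroc = object$auroc, selected_run = object$selected_run)
  class(out) <- "summary.mp_fit"
  out
}

#' @export
print.summary.mp_fit <- function(x, ...) {
  cat(sprintf("Selected run %d, auROC %.3f\n\nMetaprograms:\n",
              x$selected_run, x$auroc))
  print(x$metaprograms, row.names = FALSE)
  cat("\nStability runs:\n")
  print(x$runs, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mp_fit <- function(object, ...) {
  stats::setNames(lapply(object$metaprograms, `[[`, "genes"),
                  vapply(object$metaprograms, `[[`, "", "id"))
}

#' Score the fitted metaprograms on new cells
#'
#' @param object an `mp_fit`.
#' @param newdata a `count_matrix` (defaults to the training cells).
#' @param type `"scores"` for the rank-AUC matrix, `"active"` for the
#'   binarized calls using the fitted thresholds.
#' @param ... unused.
#' @return A cells x metaprograms matrix.
#' @export
predict.mp_fit <- function(object, newdata = NULL,
                           type = c("scores", "active"), ...) {
  type <- match.arg(type)
  cm <- if (is.null(newdata)) object$counts else newdata
  act <- score_programs(cm, metaprogram_gene_sets(object$metaprograms),
                        top_frac = object$config$auc_top_frac,
                        seed = derive_seed(object$config$master_seed,
                                           "predict"))
  if (type == "scores") {
    act$scores
  } else {
    sweep(act$scores, 2, object$activities$thresholds, ">")
  }
}

#' @export
plot.mp_fit <- function(x, ...) {
  af <- t(vapply(x$metaprograms, `[[`,
                 x$metaprograms[[1]]$active_frac, "active_frac"))
  rownames(af) <- vapply(x$metaprograms, `[[`, "", "id")
  graphics::barplot(t(af), beside = TRUE, legend.text = colnames(af),
                    ylab = "active cell fraction", ...)
  invisible(x)
}
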