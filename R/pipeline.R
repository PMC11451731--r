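# Orchestration layer: each pipeline_* function wraps the package API,
# writes plain-text outputs to a directory, and records a manifest (config
# hash, input file hashes, output paths, seed) so re-runs on identical
# inputs are reproducible and verifiable.

hash_file <- function(path) unname(tools::md5sum(path))

hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  hash_file(tmp)
}

write_manifest <- function(out_dir, stage, config, inputs, outputs) {
  manifest <- list(
    stage = stage,
    config_hash = hash_object(unclass(config)),
    input_hashes = if (length(inputs)) {
      stats::setNames(lapply(inputs, hash_file), basename(inputs))
    } else {
      list()
    },
    outputs = lapply(outputs, basename),
    master_seed = config$master_seed,
    package_version = as.character(utils::packageVersion("metaprog")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Generate a synthetic fixture directory
#'
#' Writes the mouse cohorts (MTX + sidecars), the human cohort, its survival
#' table, the homolog map, the planted program gene sets (GMT) and the truth
#' JSON to `out_dir`.
#'
#' @param spec a `synthetic_spec`.
#' @param out_dir output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
pipeline_simulate <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mouse <- generate_mouse_cohorts(spec)
  hmap <- default_homolog_map(spec)
  human <- generate_human_cohort(spec, hmap)
  p <- function(...) file.path(out_dir, ...)
  write_count_matrix(mouse$counts, p("mouse.mtx"), p("mouse_genes.tsv"),
                     p("mouse_cells.tsv"))
  write_count_matrix(human$counts, p("human.mtx"), p("human_genes.tsv"),
                     p("human_cells.tsv"))
  write_survival(human$survival, p("survival.tsv"))
  utils::write.table(data.frame(source = names(hmap),
                                target = unname(unclass(hmap))),
                     p("homologs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_sets <- mouse$truth$program_genes
  names(truth_sets) <- sprintf("P%d", seq_along(truth_sets))
  write_gmt(gene_set_collection(truth_sets), p("planted_programs.gmt"))
  jsonlite::write_json(list(
    program_genes = mouse$truth$program_genes,
    activity = mouse$truth$activity,
    human_activity = human$truth$activity,
    linear_predictor = as.list(human$truth$linear_predictor)),
    p("truth.json"), auto_unbox = FALSE, digits = NA)
  cfg <- mp_config(master_seed = spec$seed)
  manifest <- write_manifest(out_dir, "simulate", cfg, character(0),
                             list(mouse = p("mouse.mtx"),
                                  human = p("human.mtx"),
                                  survival = p("survival.tsv"),
                                  homologs = p("homologs.tsv"),
                                  truth = p("truth.json")))
  invisible(manifest)
}

#' Run metaprogram discovery and write its outputs
#'
#' @param counts a `count_matrix` or the path of an MTX file (with
#'   `<stem>_genes.tsv` / `<stem>_cells.tsv` sidecars next to it).
#' @param config an `mp_config`.
#' @param out_dir output directory.
#' @return The `mp_fit`, invisibly. Writes `metaprograms.gmt`,
#'   `factor_membership.tsv`, `runs_summary.tsv`, `activity_scores.tsv`,
#'   `activity_thresholds.tsv` and `manifest.json`.
#' @export
pipeline_discover <- function(counts, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  if (is.character(counts)) {
    stem <- sub("\\.mtx$", "", counts)
    inputs <- c(counts, paste0(stem, "_genes.tsv"), paste0(stem, "_cells.tsv"))
    counts <- read_count_matrix(inputs[1], inputs[2], inputs[3])
  }
  fit <- mp_discover(counts, config)
  p <- function(...) file.path(out_dir, ...)
  write_gmt(metaprogram_gene_sets(fit$metaprograms), p("metaprograms.gmt"))
  memb <- do.call(rbind, lapply(fit$metaprograms, function(mp) {
    do.call(rbind, lapply(mp$member_factors, function(m) {
      data.frame(metaprogram = mp$id, cohort = m$cohort, factor = m$factor)
    }))
  }))
  utils::write.table(memb, p("factor_membership.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fit$runs, p("runs_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell_id = rownames(fit$activities$scores),
               fit$activities$scores, check.names = FALSE),
    p("activity_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(metaprogram = names(fit$activities$thresholds),
               threshold = unname(fit$activities$thresholds)),
    p("activity_thresholds.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_manifest(out_dir, "discover", config, inputs,
                 list(metaprograms = p("metaprograms.gmt"),
                      runs = p("runs_summary.tsv")))
  invisible(fit)
}

#' Cluster cells into states and write labels (and embedding)
#'
#' @param fit an `mp_fit`.
#' @param out_dir output directory.
#' @param embed also write a UMAP embedding (requires `uwot`)?
#' @return The `cell_states`, invisibly.
#' @export
pipeline_states <- function(fit, out_dir, embed = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- fit$config
  st <- cell_states(fit$activities, k = cfg$knn_k,
                    resolution = cfg$louvain_resolution,
                    n_runs = cfg$n_louvain_runs,
                    seed = derive_seed(cfg$master_seed, "cell_states"),
                    embed = embed)
  p <- function(...) file.path(out_dir, ...)
  utils::write.table(
    data.frame(cell_id = names(st$labels), cluster = st$labels,
               silhouette = st$silhouette),
    p("cell_states.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cluster = rownames(st$mean_z), st$mean_z,
               check.names = FALSE),
    p("cluster_mean_z.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (embed) {
    utils::write.table(
      data.frame(cell_id = rownames(st$embedding), st$embedding),
      p("umap.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(out_dir, "states", cfg, character(0),
                 list(states = p("cell_states.tsv")))
  invisible(st)
}

#' Score mouse metaprograms on a human cohort and call shared pairs
#'
#' @param mouse_mps `gene_set_collection` of mouse metaprograms.
#' @param human_mps `gene_set_collection` of the human reference catalogue.
#' @param human_counts human `count_matrix`.
#' @param homolog_map `homolog_map` from mouse to human ids.
#' @param config an `mp_config`.
#' @param out_dir output directory.
#' @return A list with `calls` (data frame) and `network`, invisibly.
#' @export
pipeline_crossmap <- function(mouse_mps, human_mps, human_counts,
                              homolog_map, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mapped <- lapply(mouse_mps$sets, map_genes, map = homolog_map)
  mapped <- mapped[lengths(mapped) > 0]
  act_m <- score_programs(human_counts, gene_set_collection(mapped),
                          top_frac = config$auc_top_frac,
                          seed = derive_seed(config$master_seed, "cross_m"))
  act_h <- score_programs(human_counts, human_mps,
                          top_frac = config$auc_top_frac,
                          seed = derive_seed(config$master_seed, "cross_h"))
  rhos <- tumorwise_mp_correlation(act_m, act_h, human_counts$sample_id,
                                   min_cells = config$min_cells_per_tumor)
  calls <- cross_cohort_calls(list(cohort1 = rhos),
                              floor = config$cross_cohort_corr_floor,
                              alpha = config$alpha)
  net <- shared_pair_network(calls)
  p <- function(...) file.path(out_dir, ...)
  utils::write.table(calls, p("cross_cohort_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(net, p("shared_pair_network.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "crossmap", config, character(0),
                 list(calls = p("cross_cohort_calls.tsv")))
  invisible(list(calls = calls, network = net))
}

#' Score signatures on pseudobulk samples and test survival association
#'
#' @param counts a human `count_matrix`.
#' @param signatures a `gene_set_collection` (already in the human gene
#'   space).
#' @param survival survival data frame (`sample_id`, `time`, `event`).
#' @param config an `mp_config`.
#' @param out_dir output directory.
#' @return A data frame (one row per signature: `signature`, `chi2`, `p`),
#'   invisibly.
#' @export
pipeline_outcomes <- function(counts, signatures, survival, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pb <- pseudobulk(counts)
  rows <- lapply(names(signatures$sets), function(nm) {
    sc <- signature_score(pb, signatures$sets[[nm]], name = nm)
    lr <- median_split_logrank(sc, survival)
    data.frame(signature = nm, chi2 = lr$chi2, p = lr$p)
  })
  res <- do.call(rbind, rows)
  p <- function(...) file.path(out_dir, ...)
  utils::write.table(res, p("survival_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "outcomes", config, character(0),
                 list(tests = p("survival_tests.tsv")))
  invisible(res)
}
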