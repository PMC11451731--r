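#' Planted gene program
#'
#' Ground-truth unit of the synthetic generator: a set of gene indices that,
#' when the program is active in a cell, have their baseline expression rate
#' multiplied by `effect_size` before per-cell renormalization.
#'
#' @param gene_indices integer indices of member genes (may overlap between
#'   programs).
#' @param effect_size multiplicative rate boost when active (> 0; 1 means no
#'   planted signal).
#' @param activity_prob named vector of per-cohort activation probabilities
#'   (names are cohort labels; a `"human"` entry, when present, drives the
#'   human cohort, otherwise the mean of the mouse entries is used).
#' @param shared_with_human logical; planted in the human cohort through the
#'   homolog map?
#' @param hazard_coef log-hazard contribution of the standardized per-tumor
#'   pseudobulk program score to progression-free survival.
#' @return An object of class `planted_program`.
#' @export
planted_program <- function(gene_indices, effect_size, activity_prob,
                            shared_with_human = FALSE, hazard_coef = 0) {
  stopifnot(effect_size > 0, all(activity_prob >= 0 & activity_prob <= 1),
            !is.null(names(activity_prob)))
  structure(list(gene_indices = as.integer(gene_indices),
                 effect_size = as.numeric(effect_size),
                 activity_prob = activity_prob,
                 shared_with_human = isTRUE(shared_with_human),
                 hazard_coef = as.numeric(hazard_coef)),
            class = "planted_program")
}

#' Default set of planted programs
#'
#' Five disjoint 40-gene programs with effect size 6: three shared between
#' the two mouse cohorts (and with the human cohort), plus one program
#' exclusive to each cohort so the cohorts are separable by activity. The
#' first program carries a positive survival hazard.
#'
#' @param n_genes gene universe size (blocks are laid out from gene 1).
#' @param n_programs number of programs.
#' @param genes_per_program genes per program.
#' @param effect_size shared multiplicative effect.
#' @return A list of `planted_program`s.
#' @export
default_planted_programs <- function(n_genes = 2000L, n_programs = 5L,
                                     genes_per_program = 40L,
                                     effect_size = 6) {
  stopifnot(n_programs * genes_per_program <= n_genes)
  lapply(seq_len(n_programs), function(p) {
    idx <- ((p - 1L) * genes_per_program + 1L):(p * genes_per_program)
    if (p == n_programs - 1L && n_programs >= 2L) {
      prob <- c(A = 0.7, B = 0.0)
    } else if (p == n_programs && n_programs >= 2L) {
      prob <- c(A = 0.0, B = 0.7)
    } else {
      prob <- c(A = 0.45, B = 0.45)
    }
    planted_program(idx, effect_size, prob,
                    shared_with_human = prob[["A"]] > 0 && prob[["B"]] > 0,
                    hazard_coef = if (p == 1L) 1 else 0)
  })
}

#' Synthetic cohort specification
#'
#' Defines the study conditions the generator emulates: two mouse-model-like
#' cohorts ("A", "B") of malignant cells carrying shared and cohort-exclusive
#' planted programs, and a multi-tumor human-like cohort expressing the
#' shared programs through homolog ids, with progression-free survival linked
#' to program activity.
#'
#' @param n_genes genes in the universe.
#' @param n_cells_per_cohort malignant cells per mouse cohort.
#' @param programs list of `planted_program`s.
#' @param library_size_log_mean,library_size_log_sd log-normal per-cell
#'   library size parameters.
#' @param baseline_rate_shape,baseline_rate_scale Gamma parameters for the
#'   per-gene baseline rate.
#' @param n_tumors_mouse tumors (samples) per mouse cohort.
#' @param n_tumors_human tumors (patients) in the human cohort.
#' @param n_cells_per_tumor_human malignant cells per human tumor.
#' @param dispersion optional negative-binomial size parameter; `NULL` (the
#'   default) gives Poisson emission.
#' @param seed integer seed; all generator randomness derives from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L,
                           n_cells_per_cohort = 600L,
                           programs = default_planted_programs(n_genes),
                           library_size_log_mean = log(2500),
                           library_size_log_sd = 0.35,
                           baseline_rate_shape = 0.4,
                           baseline_rate_scale = 1,
                           n_tumors_mouse = 3L,
                           n_tumors_human = 12L,
                           n_cells_per_tumor_human = 40L,
                           dispersion = NULL,
                           seed = 1L) {
  stopifnot(n_genes >= 1L, n_cells_per_cohort >= 1L, n_tumors_human >= 1L,
            length(programs) >= 1L)
  for (p in programs) {
    stopifnot(inherits(p, "planted_program"))
    if (any(p$gene_indices < 1L | p$gene_indices > n_genes)) {
      stop("program gene indices outside [1, n_genes]", call. = FALSE)
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_cells_per_cohort = as.integer(n_cells_per_cohort),
                 programs = programs,
                 library_size_log_mean = library_size_log_mean,
                 library_size_log_sd = library_size_log_sd,
                 baseline_rate_shape = baseline_rate_shape,
                 baseline_rate_scale = baseline_rate_scale,
                 n_tumors_mouse = as.integer(n_tumors_mouse),
                 n_tumors_human = as.integer(n_tumors_human),
                 n_cells_per_tumor_human = as.integer(n_cells_per_tumor_human),
                 dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

mouse_gene_ids <- function(n) sprintf("g%04d", seq_len(n))
human_gene_ids <- function(n) sprintf("HG%04d", seq_len(n))

#' One-to-one mouse-to-human homolog map over the synthetic gene universe
#' @param spec a `synthetic_spec`.
#' @return A `homolog_map` covering every synthetic mouse gene.
#' @export
default_homolog_map <- function(spec) {
  structure(stats::setNames(human_gene_ids(spec$n_genes),
                            mouse_gene_ids(spec$n_genes)),
            class = c("homolog_map", "character"))
}

# Draw a counts matrix given per-cell activity. rate_g per gene baseline;
# active programs multiply member-gene rates; per-cell rates are renormalized
# to sum to 1 ("softnorm") before scaling by library size, so effects do not
# inflate totals.
draw_counts <- function(baseline, activity, programs, libsize, dispersion) {
  g <- length(baseline)
  n <- nrow(activity)
  rate <- matrix(baseline, g, n)
  for (p in seq_along(programs)) {
    act <- which(activity[, p] == 1)
    if (length(act)) {
      rate[programs[[p]]$gene_indices, act] <-
        rate[programs[[p]]$gene_indices, act] * programs[[p]]$effect_size
    }
  }
  lambda <- rate %*% diag(libsize / colSums(rate), n, n)
  counts <- if (is.null(dispersion)) {
    stats::rpois(g * n, as.vector(lambda))
  } else {
    stats::rnbinom(g * n, mu = as.vector(lambda), size = dispersion)
  }
  matrix(counts, g, n)
}

#' Generate the two mouse-like cohorts
#'
#' Counts are Poisson (optionally negative-binomial) draws around
#' `libsize_c * softnorm(baseline_g * prod(effects of active programs))`;
#' per-cell program activity is Bernoulli with the cohort's probability.
#' Deterministic given `spec$seed`.
#'
#' @param spec a `synthetic_spec`.
#' @return A list with elements `counts` (a `count_matrix` with cohorts "A"
#'   and "B") and `truth` (a `synthetic_truth`: program gene sets, per-cell
#'   binary activity and continuous dose).
#' @export
generate_mouse_cohorts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!length(spec$programs)) stop("no planted programs", call. = FALSE)
  set.seed(derive_seed(spec$seed, "mouse_cohorts"))
  g <- spec$n_genes
  nper <- spec$n_cells_per_cohort
  cohorts <- rep(c("A", "B"), each = nper)
  n <- length(cohorts)
  baseline <- stats::rgamma(g, shape = spec$baseline_rate_shape,
                            scale = spec$baseline_rate_scale)
  baseline <- pmax(baseline, 1e-8)
  activity <- sapply(spec$programs, function(p) {
    prob <- p$activity_prob[cohorts]
    prob[is.na(prob)] <- 0
    stats::rbinom(n, 1L, prob)
  })
  activity <- matrix(activity, n, length(spec$programs))
  libsize <- stats::rlnorm(n, spec$library_size_log_mean,
                           spec$library_size_log_sd)
  counts <- draw_counts(baseline, activity, spec$programs, libsize,
                        spec$dispersion)
  gid <- mouse_gene_ids(g)
  cid <- sprintf("%s_c%04d", cohorts, unlist(lapply(c(nper, nper), seq_len)))
  tumor <- sprintf("%s_t%d", cohorts,
                   (seq_len(n) - 1L) %% spec$n_tumors_mouse + 1L)
  cm <- count_matrix(counts, gid, cid, cohorts, tumor,
                     malignant = rep(TRUE, n))
  truth <- structure(list(
    program_genes = lapply(spec$programs, function(p) gid[p$gene_indices]),
    activity = stats::setNames(
      as.data.frame(activity, row.names = cid),
      sprintf("P%d", seq_along(spec$programs))),
    dose = activity,
    spec = spec), class = "synthetic_truth")
  list(counts = cm, truth = truth)
}

#' Generate the multi-tumor human-like cohort with survival outcomes
#'
#' Programs marked `shared_with_human` are planted through the homolog map.
#' Per tumor, the activation probability is jittered around the cohort-level
#' probability (Beta, concentration 6) so pseudobulk program scores vary
#' between tumors. Progression-free survival is exponential with rate
#' `exp(sum hazard_coef * standardized per-tumor mean program dose)`, censored
#' by an independent Uniform(0, 2 * mean PFS) time.
#'
#' @param spec a `synthetic_spec` (`n_tumors_human >= 2`).
#' @param homolog_map a `homolog_map` from mouse to human ids; must cover
#'   genes of shared programs.
#' @return A list with `counts` (human `count_matrix`, one cohort label
#'   "human", one sample per tumor), `truth` (a `synthetic_truth` whose
#'   `linear_predictor` holds the per-tumor true log-hazard), and `survival`
#'   (data frame: `sample_id`, `time`, `event`).
#' @export
generate_human_cohort <- function(spec, homolog_map = default_homolog_map(spec)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_tumors_human < 2L) {
    stop("need at least 2 human tumors", call. = FALSE)
  }
  set.seed(derive_seed(spec$seed, "human_cohort"))
  g <- spec$n_genes
  gid_m <- mouse_gene_ids(g)
  # human universe: mapped id where the map covers the gene, placeholder
  # (unlinkable) id otherwise
  gid_h <- ifelse(gid_m %in% names(homolog_map),
                  unname(homolog_map[gid_m]), paste0("NOHOM_", gid_m))
  shared <- vapply(spec$programs, function(p) p$shared_with_human, TRUE)
  for (p in spec$programs[shared]) {
    if (!all(gid_m[p$gene_indices] %in% names(homolog_map))) {
      stop("homolog map does not cover a shared program", call. = FALSE)
    }
  }
  nt <- spec$n_tumors_human
  npc <- spec$n_cells_per_tumor_human
  n <- nt * npc
  tumor <- rep(sprintf("pt%02d", seq_len(nt)), each = npc)
  baseline <- pmax(stats::rgamma(g, shape = spec$baseline_rate_shape,
                                 scale = spec$baseline_rate_scale), 1e-8)
  conc <- 6
  activity <- matrix(0L, n, length(spec$programs))
  for (pi in seq_along(spec$programs)) {
    p <- spec$programs[[pi]]
    if (!p$shared_with_human) next
    base_prob <- if ("human" %in% names(p$activity_prob)) {
      p$activity_prob[["human"]]
    } else {
      mean(p$activity_prob)
    }
    ptum <- if (base_prob <= 0 || base_prob >= 1) rep(base_prob, nt) else
      stats::rbeta(nt, conc * base_prob, conc * (1 - base_prob))
    activity[, pi] <- stats::rbinom(n, 1L, ptum[rep(seq_len(nt), each = npc)])
  }
  libsize <- stats::rlnorm(n, spec$library_size_log_mean,
                           spec$library_size_log_sd)
  counts <- draw_counts(baseline, activity, spec$programs, libsize,
                        spec$dispersion)
  cid <- sprintf("h_c%05d", seq_len(n))
  cm <- count_matrix(counts, gid_h, cid, rep("human", n), tumor,
                     malignant = rep(TRUE, n))
  # survival: standardized per-tumor mean dose drives the log-hazard
  hz <- vapply(spec$programs, function(p) p$hazard_coef, 0)
  tum_dose <- apply(activity, 2, function(a) tapply(a, tumor, mean))
  tum_dose <- matrix(tum_dose, nt, length(spec$programs))
  zs <- apply(tum_dose, 2, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  lp <- as.vector(matrix(zs, nt) %*% hz)
  t_event <- stats::rexp(nt, rate = exp(lp))
  cens <- stats::runif(nt, 0, 2 * mean(t_event))
  surv <- data.frame(sample_id = sprintf("pt%02d", seq_len(nt)),
                     time = pmin(t_event, cens),
                     event = as.integer(t_event <= cens))
  truth <- structure(list(
    program_genes = lapply(spec$programs, function(p) {
      if (p$shared_with_human) gid_h[p$gene_indices] else character(0)
    }),
    activity = stats::setNames(as.data.frame(activity, row.names = cid),
                               sprintf("P%d", seq_along(spec$programs))),
    dose = activity,
    linear_predictor = stats::setNames(lp, surv$sample_id),
    spec = spec), class = "synthetic_truth")
  list(counts = cm, truth = truth, survival = surv)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d programs, %d cells\n",
              length(x$program_genes), nrow(x$activity)))
  invisible(x)
}
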