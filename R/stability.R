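# auROC from scores and binary labels via the rank (Mann-Whitney) statistic;
# ties get average ranks, so a constant score gives exactly 0.5.
auroc <- function(scores, labels) {
  pos <- labels == levels(factor(labels))[2]
  r <- rank(scores)
  np <- sum(pos)
  nn <- sum(!pos)
  if (np == 0L || nn == 0L) stop("need both classes", call. = FALSE)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validated cohort-separation auROC of a metaprogram catalogue
#'
#' Trains an L2-regularized logistic regression (penalty strength 1, i.e.
#' ridge with lambda = 1/n_train) to distinguish the two cohorts from
#' per-cell metaprogram activity scores, under stratified k-fold
#' cross-validation, and computes a single auROC on the pooled out-of-fold
#' predicted probabilities. With a single metaprogram the one-feature model
#' is fit by unpenalized logistic regression.
#'
#' @param mp_activities an `activity_matrix` (or bare cells x programs score
#'   matrix).
#' @param cohort_labels per-cell labels; exactly two distinct values.
#' @param folds number of CV folds.
#' @param seed integer seed for fold assignment.
#' @return The pooled out-of-fold auROC in `[0, 1]`.
#' @export
score_run <- function(mp_activities, cohort_labels, folds = 5L, seed = 1L) {
  x <- if (inherits(mp_activities, "activity_matrix")) {
    mp_activities$scores
  } else {
    as.matrix(mp_activities)
  }
  y <- factor(cohort_labels)
  if (nlevels(y) != 2L) stop("exactly two cohorts required", call. = FALSE)
  if (min(table(y)) < folds) stop("a cohort has fewer cells than folds",
                                  call. = FALSE)
  n <- length(y)
  set.seed(seed)
  fold <- integer(n)
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  prob <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    te <- !tr
    if (all(apply(x[tr, , drop = FALSE], 2, stats::sd) == 0)) {
      # uninformative features: constant predicted probability
      prob[te] <- mean(y[tr] == levels(y)[2])
    } else if (ncol(x) >= 2L) {
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                            family = "binomial", alpha = 0,
                            lambda = 1 / sum(tr), standardize = FALSE)
      prob[te] <- as.numeric(stats::predict(fit, x[te, , drop = FALSE],
                                            type = "response"))
    } else {
      df <- data.frame(y = y[tr], x1 = x[tr, 1])
      fit <- suppressWarnings(stats::glm(y ~ x1, df, family = stats::binomial()))
      prob[te] <- suppressWarnings(
        stats::predict(fit, data.frame(x1 = x[te, 1]), type = "response"))
    }
  }
  auroc(prob, y)
}

#' Select the median-auROC run
#'
#' Runs are sorted by auROC; with an odd count the middle run is returned,
#' with an even count the lower of the two middle values (an actual run must
#' be selected, not an interpolation). Runs tied at the median value resolve
#' to the smallest run index.
#'
#' @param runs list of run records, each with `auroc` and `run_index`.
#' @return The selected run record.
#' @export
select_median_run <- function(runs) {
  if (!length(runs)) stop("no scored runs", call. = FALSE)
  au <- vapply(runs, function(r) as.numeric(r$auroc), 0)
  idx <- vapply(runs, function(r) as.integer(r$run_index), 0L)
  ord <- order(au, idx)
  med_pos <- ord[floor((length(runs) + 1) / 2)]
  med_val <- au[med_pos]
  tied <- which(au == med_val)
  runs[[tied[which.min(idx[tied])]]]
}

#' Repeat discovery across runs and select the median-auROC run
#'
#' Executes the full per-run procedure (per-cohort NMF, gene prioritization,
#' activity scoring, metaprogram assembly, cohort-separation auROC)
#' `config$n_stability_runs` times with independently derived seeds, and
#' selects the run with the median auROC. Runs yielding zero metaprograms
#' are recorded with `auroc = NA` and excluded from the median with a
#' warning. Results are independent of execution order.
#'
#' @param counts a filtered malignant-cell `count_matrix` with exactly two
#'   cohorts.
#' @param config an `mp_config`.
#' @return A list: `selected` (the median run record: `run_index`, `seed`,
#'   `metaprograms`, `activities`, `auroc`) and `runs` (all run records).
#' @export
run_stability <- function(counts, config) {
  stopifnot(inherits(counts, "count_matrix"), inherits(config, "mp_config"))
  cohorts <- sort(unique(counts$cohort))
  if (length(cohorts) != 2L) stop("exactly two cohorts required", call. = FALSE)
  runs <- lapply(seq_len(config$n_stability_runs), function(r) {
    run_seed <- derive_seed(config$master_seed, "stability_run", r)
    fsets <- lapply(cohorts, function(ch) {
      fs <- run_nmf(counts, ch, config$n_factors,
                    derive_seed(run_seed, paste0("nmf_", ch)))
      prioritize_factor_genes(fs, counts,
                              z_thr = config$loading_z_threshold,
                              corr_thr = config$coexpr_corr_threshold,
                              min_genes = config$min_prioritized_genes)
    })
    asm <- assemble_metaprograms(fsets, counts, config, seed = run_seed)
    au <- if (length(asm$metaprograms)) {
      score_run(asm$activities, counts$cohort, folds = config$cv_folds,
                seed = derive_seed(run_seed, "cv_folds"))
    } else {
      NA_real_
    }
    list(run_index = r, seed = run_seed, metaprograms = asm$metaprograms,
         activities = asm$activities, factor_sets = fsets, auroc = au)
  })
  scored <- runs[!vapply(runs, function(r) is.na(r$auroc), TRUE)]
  if (length(scored) < length(runs)) {
    warning(sprintf("%d run(s) yielded zero metaprograms; excluded from %s",
                    length(runs) - length(scored), "median selection"),
            call. = FALSE)
  }
  if (!length(scored)) stop("every run yielded zero metaprograms",
                            call. = FALSE)
  list(selected = select_median_run(scored), runs = runs)
}

#' Summarize stability runs
#' @param runs list of run records.
#' @return Data frame: `run_index`, `seed`, `n_metaprograms`, `auroc`.
#' @export
stability_summary <- function(runs) {
  data.frame(run_index = vapply(runs, `[[`, 0L, "run_index"),
             seed = vapply(runs, `[[`, 0L, "seed"),
             n_metaprograms = vapply(runs, function(r)
               length(r$metaprograms), 0L),
             auroc = vapply(runs, `[[`, 0, "auroc"))
}
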