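#' Tumor-wise Spearman correlation between two metaprogram catalogues
#'
#' Both catalogues must be scored on the same cells (for mouse-vs-human
#' comparisons, pass mouse metaprogram genes through the homolog map and
#' score them on the human cells first). Within each tumor with at least
#' `min_cells` cells, the Spearman correlation of every (catalogue A,
#' catalogue B) program pair's per-cell scores is computed; a constant score
#' vector within a tumor gives `NA` for its pairs. Smaller tumors are
#' skipped with a warning.
#'
#' @param activities_a,activities_b `activity_matrix` objects over the same
#'   cells (rows aligned).
#' @param sample_ids per-cell tumor/biopsy id.
#' @param min_cells minimum cells per usable tumor.
#' @return A 3-d array `[program_a, program_b, tumor]` of Spearman rhos.
#' @export
tumorwise_mp_correlation <- function(activities_a, activities_b, sample_ids,
                                     min_cells = 20L) {
  a <- activities_a$scores
  b <- activities_b$scores
  stopifnot(nrow(a) == nrow(b), nrow(a) == length(sample_ids))
  tum <- table(sample_ids)
  usable <- names(tum)[tum >= min_cells]
  if (length(usable) < length(tum)) {
    warning(sprintf("skipping %d tumor(s) with fewer than %d cells",
                    length(tum) - length(usable), min_cells), call. = FALSE)
  }
  if (!length(usable)) stop("no tumor has enough cells", call. = FALSE)
  out <- array(NA_real_, dim = c(ncol(a), ncol(b), length(usable)),
               dimnames = list(colnames(a), colnames(b), usable))
  for (t in usable) {
    idx <- sample_ids == t
    out[, , t] <- suppressWarnings(
      stats::cor(a[idx, , drop = FALSE], b[idx, , drop = FALSE],
                 method = "spearman"))
  }
  out
}

#' One-sided Wilcoxon signed-rank test against a correlation floor
#'
#' Tests whether a set of tumor-wise correlations is significantly above
#' `floor`: a one-sided signed-rank test of `rho - floor > 0`. Zeros are
#' dropped per the standard convention; for n <= 25 the p-value is exact
#' (computed by dynamic programming over the signed midranks, hence valid
#' under ties), otherwise a normal approximation with continuity and tie
#' correction is used.
#'
#' @param rhos numeric vector of correlations (`NA`s dropped; at least 3
#'   non-`NA` values required).
#' @param floor the correlation floor.
#' @return The one-sided p-value.
#' @examples
#' wilcoxon_above(c(0.5, 0.6, 0.7, 0.8, 0.9), 0.2)  # exact 1/32
#' @export
wilcoxon_above <- function(rhos, floor = 0.2) {
  x <- rhos[!is.na(rhos)] - floor
  if (length(x) < 3L) stop("need at least 3 non-NA correlations",
                           call. = FALSE)
  x <- x[x != 0]
  if (!length(x)) return(1)
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  n <- length(x)
  if (n <= 25L) {
    # exact distribution of W under random signs, via convolution over the
    # doubled midranks (integers even under ties)
    d <- as.integer(round(2 * r))
    counts <- c(1, rep(0, sum(d)))  # counts[s + 1] = #subsets with sum s
    for (di in d) {
      shifted <- c(rep(0, di), counts[seq_len(length(counts) - di)])
      counts <- counts + shifted
    }
    wd <- as.integer(round(2 * w))
    sum(counts[(wd + 1):length(counts)]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    stats::pnorm((w - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
  }
}

#' Call significantly shared metaprogram pairs within cohorts
#'
#' For every program pair and cohort, retains the median tumor-wise
#' correlation and calls the pair significant when the tumor-wise
#' correlations are significantly above the floor (one-sided Wilcoxon
#' p < alpha). No multiple-testing correction is applied by default,
#' matching the published procedure; set `adjust = "BH"` for
#' Benjamini-Hochberg within each cohort.
#'
#' @param rho_arrays named list (one per cohort) of arrays from
#'   [tumorwise_mp_correlation()].
#' @param floor correlation floor.
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data frame: `mp_a`, `mp_b`, `cohort`, `n_tumors`, `median_rho`,
#'   `p_value`, `significant`.
#' @export
cross_cohort_calls <- function(rho_arrays, floor = 0.2, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  out <- list()
  for (co in names(rho_arrays)) {
    arr <- rho_arrays[[co]]
    rows <- list()
    for (i in seq_len(dim(arr)[1])) {
      for (j in seq_len(dim(arr)[2])) {
        rh <- arr[i, j, ]
        nr <- sum(!is.na(rh))
        p <- if (nr >= 3L) wilcoxon_above(rh, floor) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          mp_a = dimnames(arr)[[1]][i], mp_b = dimnames(arr)[[2]][j],
          cohort = co, n_tumors = nr,
          median_rho = stats::median(rh, na.rm = TRUE), p_value = p)
      }
    }
    df <- do.call(rbind, rows)
    if (adjust == "BH") df$p_value <- stats::p.adjust(df$p_value, "BH")
    df$significant <- !is.na(df$p_value) & df$p_value < alpha
    out[[co]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-cohort shared-pair network
#'
#' Counts, per metaprogram pair, the cohorts in which the pair was called
#' significantly positively correlated, and keeps pairs significant in at
#' least one cohort.
#'
#' @param results data frame from [cross_cohort_calls()].
#' @return Data frame: `mp_a`, `mp_b`, `n_significant_cohorts` (edge list).
#' @export
shared_pair_network <- function(results) {
  agg <- stats::aggregate(significant ~ mp_a + mp_b, data = results, FUN = sum)
  names(agg)[3] <- "n_significant_cohorts"
  agg <- agg[agg$n_significant_cohorts >= 1L, , drop = FALSE]
  agg <- agg[order(agg$mp_a, agg$mp_b), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
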