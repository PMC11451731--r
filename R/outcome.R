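#' Pseudobulk expression per sample
#'
#' Sums counts over all cells of each sample, then normalizes per sample as
#' `log2(CPM + 0.001)`. Pre-log CPM columns sum to 1e6 exactly.
#'
#' @param counts a `count_matrix`.
#' @return A genes x samples numeric matrix.
#' @export
pseudobulk <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  samples <- sort(unique(counts$sample_id))
  ind <- Matrix::sparseMatrix(
    i = seq_along(counts$sample_id),
    j = match(counts$sample_id, samples), x = 1,
    dims = c(length(counts$sample_id), length(samples)))
  sums <- as.matrix(counts$counts %*% ind)
  colnames(sums) <- samples
  tot <- colSums(sums)
  if (any(tot == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(samples[tot == 0], collapse = ", "), call. = FALSE)
  }
  cpm <- sweep(sums, 2, tot / 1e6, "/")
  log2(cpm + 0.001)
}

#' Mean z-score signature scores per sample
#'
#' z-scores each signature gene across samples (sample sd), then averages
#' over the signature's genes per sample. Genes absent from the matrix are
#' omitted; an empty intersection is an error naming the signature.
#'
#' @param pb genes x samples pseudobulk matrix (from [pseudobulk()]).
#' @param signature character vector of gene ids.
#' @param name signature name used in messages.
#' @return A named per-sample numeric vector of mean z-scores.
#' @export
signature_score <- function(pb, signature, name = "signature") {
  stopifnot(ncol(pb) >= 2L)
  genes <- intersect(signature, rownames(pb))
  if (!length(genes)) {
    stop(sprintf("signature '%s' has no genes in the pseudobulk matrix",
                 name), call. = FALSE)
  }
  sub <- pb[genes, , drop = FALSE]
  sdv <- apply(sub, 1, stats::sd)
  z <- (sub - rowMeans(sub)) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  colMeans(z)
}

#' Spearman correlation between two signature score vectors
#'
#' @param scores_a,scores_b per-sample scores (aligned; >= 4 pairs).
#' @return A list with `rho` and `p` (two-sided; exact for small n without
#'   ties via [stats::cor.test()]). Constant input gives `NA` for both.
#' @export
signature_correlation <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 4L)
  if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(scores_a, scores_b,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Median-split log-rank comparison of progression-free survival
#'
#' Samples are split into High (score >= median) and Low (score < median)
#' groups and compared with the standard log-rank (Mantel-Cox) test: the sum
#' over event times of observed minus expected events in the High group,
#' with hypergeometric variance and the usual grouped handling of tied event
#' times, referred to a 1-df chi-square.
#'
#' @param scores named per-sample signature scores.
#' @param survival data frame with columns `sample_id`, `time`, `event`
#'   (0/1); every scored sample must have a record.
#' @return A list: `groups` (named factor High/Low), `chi2`, `p`, `fit` (the
#'   underlying `survival::survdiff` object).
#' @export
median_split_logrank <- function(scores, survival) {
  stopifnot(!is.null(names(scores)),
            all(c("sample_id", "time", "event") %in% names(survival)))
  miss <- setdiff(names(scores), survival$sample_id)
  if (length(miss)) {
    stop("no survival record for sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  grp <- factor(ifelse(scores >= stats::median(scores), "High", "Low"),
                levels = c("Low", "High"))
  names(grp) <- names(scores)
  if (min(table(grp)) < 2L) {
    stop("degenerate median split: fewer than 2 samples in a group",
         call. = FALSE)
  }
  sv <- survival[match(names(scores), survival$sample_id), ]
  sd_fit <- survival::survdiff(
    survival::Surv(sv$time, sv$event) ~ grp)
  chi2 <- sd_fit$chisq
  list(groups = grp, chi2 = unname(chi2),
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE), fit = sd_fit)
}

#' Read / write a survival table TSV (`sample_id`, `time`, `event`)
#' @param path TSV path.
#' @return `read_survival()` returns the validated data frame.
#' @export
read_survival <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("survival TSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$time < 0)) stop("negative survival time", call. = FALSE)
  if (!all(tab$event %in% c(0, 1))) {
    stop("event must be 0/1", call. = FALSE)
  }
  tab[need]
}

#' @rdname read_survival
#' @param survival the survival data frame.
#' @export
write_survival <- function(survival, path) {
  utils::write.table(survival, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
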