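#' Annotated sparse count matrix
#'
#' The universal input container of the pipeline: a sparse gene x cell matrix
#' of non-negative integer counts with per-cell annotations (cohort label,
#' tumor/sample of origin, malignant flag). Identifiers are case-sensitive
#' strings and matching between files is exact.
#'
#' @param counts a matrix or `Matrix::sparseMatrix` of non-negative integer
#'   counts, genes in rows, cells in columns.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of unique cell identifiers (columns).
#' @param cohort per-cell cohort/model label.
#' @param sample_id per-cell tumor or biopsy of origin.
#' @param malignant per-cell logical flag.
#' @return An object of class `count_matrix`.
#' @examples
#' cm <- count_matrix(matrix(c(3, 0, 0, 1), 2), c("g1", "g2"), c("c1", "c2"),
#'                    cohort = c("A", "A"), sample_id = c("t1", "t1"),
#'                    malignant = c(TRUE, TRUE))
#' dim(cm)
#' @export
count_matrix <- function(counts, gene_ids, cell_ids, cohort, sample_id,
                         malignant = rep(TRUE, length(cell_ids))) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  cohort <- as.character(cohort)
  sample_id <- as.character(sample_id)
  malignant <- as.logical(malignant)

  if (nrow(counts) != length(gene_ids)) {
    stop("dimension mismatch: ", nrow(counts), " matrix rows vs ",
         length(gene_ids), " gene ids", call. = FALSE)
  }
  if (ncol(counts) != length(cell_ids)) {
    stop("dimension mismatch: ", ncol(counts), " matrix columns vs ",
         length(cell_ids), " cell ids", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids", call. = FALSE)
  if (length(cohort) != length(cell_ids) ||
      length(sample_id) != length(cell_ids) ||
      length(malignant) != length(cell_ids)) {
    stop("per-cell annotations must match the number of cells", call. = FALSE)
  }
  if (anyNA(cohort) || anyNA(sample_id)) {
    stop("every cell needs a cohort and a sample_id", call. = FALSE)
  }
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != floor(v)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cohort = cohort, sample_id = sample_id,
                 malignant = malignant),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells\n", nrow(x$counts),
              ncol(x$counts)))
  cat("  cohorts:   ", paste(sprintf("%s (%d)", names(table(x$cohort)),
                                     table(x$cohort)), collapse = ", "), "\n")
  cat(sprintf("  samples:    %d; malignant cells: %d\n",
              length(unique(x$sample_id)), sum(x$malignant)))
  invisible(x)
}

#' Subset a count matrix
#'
#' @param x a `count_matrix`.
#' @param genes gene ids or indices to keep (default all).
#' @param cells cell ids, indices or a logical mask to keep (default all).
#' @return A `count_matrix` restricted to the selection, order preserved as
#'   given.
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  gi <- if (is.null(genes)) seq_along(x$gene_ids) else {
    if (is.character(genes)) match(genes, x$gene_ids) else genes
  }
  ci <- if (is.null(cells)) seq_along(x$cell_ids) else {
    if (is.character(cells)) match(cells, x$cell_ids)
    else if (is.logical(cells)) which(cells)
    else cells
  }
  if (anyNA(gi)) stop("unknown gene id in selection", call. = FALSE)
  if (anyNA(ci)) stop("unknown cell id in selection", call. = FALSE)
  count_matrix(x$counts[gi, ci, drop = FALSE], x$gene_ids[gi], x$cell_ids[ci],
               x$cohort[ci], x$sample_id[ci], x$malignant[ci])
}

#' Restrict to malignant cells
#' @param x a `count_matrix`.
#' @return A `count_matrix` with only cells flagged malignant.
#' @export
malignant_cells <- function(x) subset_cells(x, cells = x$malignant)

#' Read a count matrix from Matrix Market + TSV sidecars
#'
#' Expects a 1-based coordinate MTX file of integer counts, a gene sidecar TSV
#' with a `gene_id` column and a cell sidecar TSV with `cell_id`, `cohort`,
#' `sample_id` and `malignant` columns; row/column order follows the sidecars.
#'
#' @param mtx_path,genes_path,cells_path file paths.
#' @return A validated `count_matrix`.
#' @export
read_count_matrix <- function(mtx_path, genes_path, cells_path) {
  m <- tryCatch(Matrix::readMM(mtx_path),
                error = function(e) stop("format error reading MTX: ",
                                         conditionMessage(e), call. = FALSE))
  if (nrow(m) == 0L || ncol(m) == 0L) {
    stop("format error: MTX header declares an empty matrix", call. = FALSE)
  }
  genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  cells <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(genes)) {
    stop("gene sidecar is missing required column 'gene_id'", call. = FALSE)
  }
  need <- c("cell_id", "cohort", "sample_id", "malignant")
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    stop("cell sidecar is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(genes) != nrow(m) || nrow(cells) != ncol(m)) {
    stop(sprintf(
      "format error: MTX is %d x %d but sidecars describe %d genes, %d cells",
      nrow(m), ncol(m), nrow(genes), nrow(cells)), call. = FALSE)
  }
  count_matrix(m, genes$gene_id, cells$cell_id, cells$cohort,
               cells$sample_id, as.logical(cells$malignant))
}

#' Write a count matrix as Matrix Market + TSV sidecars
#'
#' @param x a `count_matrix`.
#' @param mtx_path,genes_path,cells_path output file paths.
#' @return The paths, invisibly.
#' @export
write_count_matrix <- function(x, mtx_path, genes_path, cells_path) {
  stopifnot(inherits(x, "count_matrix"))
  Matrix::writeMM(x$counts, mtx_path)
  utils::write.table(data.frame(gene_id = x$gene_ids),
                     genes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell_id = x$cell_ids, cohort = x$cohort,
               sample_id = x$sample_id, malignant = x$malignant),
    cells_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(mtx_path, genes_path, cells_path))
}

# Library-size normalization used throughout: log1p of counts-per-10k per
# cell. Returns a dense genes x cells matrix; zero-total cells stay all-zero.
#' Normalize counts to log1p counts-per-10k
#'
#' @param x a `count_matrix` (or bare matrix of counts).
#' @return A dense numeric matrix, genes x cells.
#' @export
normalize_log_cp10k <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else x
  tot <- Matrix::colSums(m)
  tot[tot == 0] <- 1
  out <- as.matrix(m %*% Matrix::Diagonal(x = 1e4 / tot))
  dimnames(out) <- dimnames(m)
  log1p(out)
}
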