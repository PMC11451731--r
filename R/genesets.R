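#' Gene set collection
#'
#' A named list of ordered, duplicate-free gene lists with optional per-set
#' descriptions; the container for factor gene lists, metaprogram consensus
#' lists and hand-built signatures.
#'
#' @param sets named list of character vectors.
#' @param description named character vector of per-set free text (recycled to
#'   `""` when absent).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("set names must be present and unique", call. = FALSE)
  }
  if (any(!lengths(sets))) stop("each gene set must be non-empty", call. = FALSE)
  sets <- lapply(sets, as.character)
  if (any(vapply(sets, anyDuplicated, 0L) > 0L)) {
    stop("duplicate genes within a set", call. = FALSE)
  }
  if (is.null(description)) description <- stats::setNames(
    rep("", length(sets)), names(sets))
  structure(list(sets = sets,
                 description = description[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n", length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets in GMT format
#'
#' Standard GMT: `name TAB description TAB gene TAB gene ...`. Duplicate genes
#' within a set are dropped with a warning; order is otherwise preserved.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("format error in GMT at line %d: fewer than 3 fields", i),
           call. = FALSE)
    }
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': dropping %d duplicate gene(s)",
                      f[1], sum(duplicated(genes))), call. = FALSE)
      genes <- genes[!duplicated(genes)]
    }
    sets[[f[1]]] <- genes
    desc[[f[1]]] <- f[2]
  }
  gene_set_collection(sets, desc)
}

#' Write gene sets in GMT format
#'
#' @param x a `gene_set_collection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, x$description[[nm]], x$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Resolve a raw homolog table to a one-to-one mapping
#'
#' Sources with several candidate targets keep the alphabetically first target
#' that is present in `genes_present`; targets absent from `genes_present` are
#' dropped, so unmapped genes are simply omitted from downstream signature
#' calculations.
#'
#' @param raw_pairs a two-column data frame (or matrix) of `source`, `target`
#'   gene id pairs; one-to-many relations allowed.
#' @param genes_present character vector: the target-side gene universe.
#' @return A named character vector (class `homolog_map`): source -> target.
#' @examples
#' resolve_homologs(data.frame(source = c("Gsta4", "Gsta4"),
#'                             target = c("GSTA4", "GSTA3")),
#'                  c("GSTA3", "GSTA4"))
#' @export
resolve_homologs <- function(raw_pairs, genes_present) {
  rp <- as.data.frame(raw_pairs, stringsAsFactors = FALSE)
  names(rp)[1:2] <- c("source", "target")
  rp <- rp[rp$target %in% genes_present, , drop = FALSE]
  out <- character(0)
  if (nrow(rp)) {
    rp <- rp[order(rp$source, rp$target), , drop = FALSE]
    rp <- rp[!duplicated(rp$source), , drop = FALSE]
    out <- stats::setNames(rp$target, rp$source)
  }
  if (!length(out)) {
    warning("homolog map is empty after resolution", call. = FALSE)
  }
  structure(out, class = c("homolog_map", "character"))
}

#' Read a two-column homolog TSV (columns `source`, `target`)
#' @param path TSV path.
#' @param genes_present target-side gene universe for resolution.
#' @return A `homolog_map`.
#' @export
read_homolog_map <- function(path, genes_present) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("source", "target") %in% names(tab))) {
    stop("homolog TSV must have columns 'source' and 'target'", call. = FALSE)
  }
  resolve_homologs(tab, genes_present)
}

#' Translate a gene list through a homolog map
#' @param genes character vector of source-side gene ids.
#' @param map a `homolog_map`.
#' @return The mapped target ids (unmapped genes dropped, duplicates removed).
#' @export
map_genes <- function(genes, map) {
  out <- unname(map[genes])
  unique(out[!is.na(out)])
}
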