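test_that("count_matrix validates identifiers, annotations and counts", {
  m <- matrix(c(3, 0, 0, 1), 2)
  cm <- count_matrix(m, c("g1", "g2"), c("c1", "c2"), c("A", "B"),
                     c("t1", "t2"), c(TRUE, TRUE))
  expect_equal(dim(cm), c(2L, 2L))
  expect_equal(as.matrix(cm$counts), matrix(c(3, 0, 0, 1), 2),
               ignore_attr = TRUE)
  expect_error(count_matrix(m, c("g1", "g1"), c("c1", "c2"), c("A", "B"),
                            c("t1", "t2")), "duplicate gene")
  expect_error(count_matrix(m, c("g1", "g2"), c("c1", "c1"), c("A", "B"),
                            c("t1", "t2")), "duplicate cell")
  expect_error(count_matrix(matrix(c(-1, 0, 0, 1), 2), c("g1", "g2"),
                            c("c1", "c2"), c("A", "B"), c("t1", "t2")),
               "non-negative integer")
  expect_error(count_matrix(matrix(c(0.5, 0, 0, 1), 2), c("g1", "g2"),
                            c("c1", "c2"), c("A", "B"), c("t1", "t2")),
               "non-negative integer")
  expect_error(count_matrix(m, c("g1", "g2"), c("c1", "c2"),
                            c("A", NA), c("t1", "t2")), "cohort")
  expect_error(count_matrix(m, c("g1", "g2", "g3"), c("c1", "c2"),
                            c("A", "B"), c("t1", "t2")), "mismatch")
})

test_that("MTX + sidecar round trip preserves counts, ids and annotations", {
  set.seed(42)
  cm <- tiny_cm(matrix(rpois(40, 2), 5), cohort = rep(c("A", "B"), each = 4))
  d <- withr::local_tempdir()
  p <- function(f) file.path(d, f)
  write_count_matrix(cm, p("x.mtx"), p("x_genes.tsv"), p("x_cells.tsv"))
  back <- read_count_matrix(p("x.mtx"), p("x_genes.tsv"), p("x_cells.tsv"))
  expect_identical(as.matrix(back$counts), as.matrix(cm$counts))
  expect_identical(back$gene_ids, cm$gene_ids)
  expect_identical(back$cell_ids, cm$cell_ids)
  expect_identical(back$cohort, cm$cohort)
  expect_identical(back$sample_id, cm$sample_id)
  expect_identical(back$malignant, cm$malignant)
})

test_that("read_count_matrix rejects malformed inputs with clear messages", {
  d <- withr::local_tempdir()
  p <- function(f) file.path(d, f)
  cm <- tiny_cm()
  write_count_matrix(cm, p("x.mtx"), p("x_genes.tsv"), p("x_cells.tsv"))

  # sidecar/matrix dimension mismatch
  writeLines(c("gene_id", "g1"), p("short_genes.tsv"))
  expect_error(read_count_matrix(p("x.mtx"), p("short_genes.tsv"),
                                 p("x_cells.tsv")), "format error")

  # missing required cell column
  cells <- read.delim(p("x_cells.tsv"))
  write.table(cells[setdiff(names(cells), "cohort")], p("nocohort.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_count_matrix(p("x.mtx"), p("x_genes.tsv"),
                                 p("nocohort.tsv")), "cohort")

  # empty matrix header
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "0 0 0"), p("empty.mtx"))
  expect_error(read_count_matrix(p("empty.mtx"), p("x_genes.tsv"),
                                 p("x_cells.tsv")), "format error")
})

test_that("GMT parsing round-trips, deduplicates and reports bad lines", {
  d <- withr::local_tempdir()
  f <- file.path(d, "sets.gmt")

  writeLines("S1\tdesc\tA\tB", f)
  expect_identical(read_gmt(f)$sets, list(S1 = c("A", "B")))

  writeLines("S1\tdesc\tA\tA\tB", f)
  expect_warning(gs <- read_gmt(f), "duplicate")
  expect_identical(gs$sets$S1, c("A", "B"))

  writeLines(c("S1\tdesc\tA\tB", "S2\tdesc"), f)
  expect_error(read_gmt(f), "line 2")

  col <- gene_set_collection(list(alpha = c("x", "y", "z"), beta = "w"),
                             c(alpha = "first", beta = "second"))
  write_gmt(col, f)
  back <- read_gmt(f)
  expect_identical(back$sets, col$sets)
  expect_identical(back$description, col$description)
})

test_that("homolog resolution keeps alphabetically first present target", {
  expect_identical(
    unclass(resolve_homologs(data.frame(source = "Tyr", target = "TYR"),
                             c("TYR", "OTHER")))[["Tyr"]], "TYR")
  m <- resolve_homologs(data.frame(source = c("Gsta4", "Gsta4"),
                                   target = c("GSTA4", "GSTA3")),
                        c("GSTA3", "GSTA4"))
  expect_identical(unclass(m)[["Gsta4"]], "GSTA3")
  expect_warning(
    m0 <- resolve_homologs(data.frame(source = "Dct", target = "DCT"),
                           c("TYR")), "empty")
  expect_length(m0, 0)
  # targets absent from the universe are dropped even when another exists
  m2 <- resolve_homologs(data.frame(source = c("Gsta4", "Gsta4"),
                                    target = c("GSTA3", "GSTA4")),
                         c("GSTA4"))
  expect_identical(unclass(m2)[["Gsta4"]], "GSTA4")
})

test_that("config validates fields and survives a JSON round trip", {
  expect_error(mp_config(min_gene_cell_frac = 0), "fraction")
  expect_error(mp_config(alpha = 1), "fraction")
  expect_error(mp_config(n_factors = 0), "count")
  cfg <- mp_config(n_stability_runs = 3, master_seed = 99)
  f <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, f)
  expect_equal(read_config(f), cfg)
})

test_that("seed derivation is deterministic, stage-distinct and below 2^31", {
  s1 <- derive_seed(42L, "nmf", 1L)
  expect_identical(s1, derive_seed(42L, "nmf", 1L))
  expect_false(s1 == derive_seed(42L, "nmf", 2L))
  expect_false(s1 == derive_seed(42L, "louvain", 1L))
  expect_false(s1 == derive_seed(43L, "nmf", 1L))
  seeds <- vapply(1:200, function(i) derive_seed(7L, "stage", i), 0L)
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_false(any(duplicated(seeds)))
})
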