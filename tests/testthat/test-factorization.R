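test_that("detection filter implements the at-least-1%-of-cells rule", {
  set.seed(1)
  m <- matrix(rpois(100 * 100, 0.5), 100)
  m[1, ] <- 0                  # all-zero gene
  m[2, ] <- c(1, rep(0, 99))   # exactly 1 of 100 cells
  cm <- count_matrix(m, sprintf("g%03d", 1:100), sprintf("c%03d", 1:100),
                     rep(c("A", "B"), each = 50), rep("t1", 100))
  kept <- filter_genes(cm, 0.01)$gene_ids
  expect_false("g001" %in% kept)
  expect_true("g002" %in% kept)   # "at least 1%" is inclusive
  expect_identical(filter_genes(cm, 0)$gene_ids, cm$gene_ids)
  allzero <- count_matrix(matrix(0L, 2, 3), c("a", "b"), c("x", "y", "z"),
                          rep("A", 3), rep("t", 3))
  expect_error(filter_genes(allzero, 0.5), "no genes")
})

test_that("NMF recovers an exact low-rank matrix and is deterministic", {
  # rank-1 counts: outer product structure survives the log1p/CP10k
  # transform only approximately, so factorize a rank-1 normalized matrix
  # by constructing counts whose normalized matrix is exactly rank 1
  w <- c(4, 2, 1, 0, 3)
  cm <- count_matrix(outer(w, c(2L, 3L, 5L, 4L)), sprintf("g%d", 1:5),
                     sprintf("c%d", 1:4), rep("A", 4), rep("t", 4))
  fs1 <- run_nmf(cm, "A", 1, seed = 7)
  expect_lt(fs1$rel_error, 1e-5)
  fs2 <- run_nmf(cm, "A", 1, seed = 7)
  expect_identical(fs1$loadings, fs2$loadings)
  expect_identical(fs1$cell_weights, fs2$cell_weights)
  expect_error(run_nmf(cm, "A", 10, seed = 1), "exceeds")
  expect_error(run_nmf(cm, "Z", 1, seed = 1), "not present")
})

test_that("block-diagonal programs land on separate factors", {
  set.seed(3)
  n <- 60
  m <- matrix(rpois(20 * n, 0.2), 20)
  m[1:10, 1:30] <- m[1:10, 1:30] + matrix(rpois(300, 20), 10)
  m[11:20, 31:60] <- m[11:20, 31:60] + matrix(rpois(300, 20), 10)
  cm <- count_matrix(m, sprintf("g%02d", 1:20), sprintf("c%02d", 1:n),
                     rep("A", n), rep("t", n))
  fs <- run_nmf(cm, "A", 2, seed = 5)
  top <- apply(fs$loadings, 2, function(w) order(-w)[1:10])
  blocks <- list(1:10, 11:20)
  hit <- sapply(1:2, function(j) {
    max(sapply(blocks, function(b) length(intersect(top[, j], b))))
  })
  expect_true(all(hit == 10))
  # and the two factors cover different blocks
  expect_false(setequal(top[, 1], top[, 2]))
})

test_that("reconstruction error is non-increasing across ranks", {
  set.seed(8)
  m <- matrix(rpois(40 * 50, 2), 40)
  cm <- count_matrix(m, sprintf("g%02d", 1:40), sprintf("c%02d", 1:50),
                     rep("A", 50), rep("t", 50))
  scan <- elbow_rank_scan(cm, "A", c(1, 2, 4, 8), seed = 2)
  expect_equal(nrow(scan), 4)
  expect_true(all(diff(scan$rel_error) <= 1e-8))
  single <- elbow_rank_scan(cm, "A", 3, seed = 2)
  expect_equal(nrow(single), 1)
})

test_that("elbow scan on planted programs drops fastest by the true rank", {
  spec <- small_spec(seed = 17, n_programs = 3)
  sim <- generate_mouse_cohorts(spec)
  filt <- filter_genes(malignant_cells(sim$counts), 0.01)
  scan <- elbow_rank_scan(filt, "A", 1:6, seed = 4)
  drops <- -diff(scan$rel_error)
  expect_lte(which.max(drops) + 1, 3 + 1)
})

test_that("loading z-scores are standardized per gene across factors", {
  set.seed(2)
  W <- matrix(runif(50 * 6), 50)
  W[7, ] <- 0.3  # constant loading row
  z <- metaprog:::zscore_loadings(W)
  expect_equal(rowMeans(z[-7, ]), rep(0, 49), tolerance = 1e-12)
  expect_equal(apply(z[-7, ], 1, sd), rep(1, 49), tolerance = 1e-12)
  expect_equal(z[7, ], rep(0, 6))
})

test_that("largest component selection matches a union-find oracle", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(3:50, 1)
    cmat <- matrix(0, n, n)
    rownames(cmat) <- colnames(cmat) <- sprintf("g%02d", seq_len(n))
    pairs <- which(upper.tri(cmat), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < 0.08
    cmat[pairs[on, , drop = FALSE]] <- 0.9
    cmat <- pmax(cmat, t(cmat))
    diag(cmat) <- 1
    loadings <- runif(n)
    got <- metaprog:::largest_corr_component(cmat, 0.4, loadings)
    edges <- pairs[on, , drop = FALSE]
    comp <- union_find_components(n, edges)
    sizes <- table(comp)
    expect_equal(length(got), max(sizes))
    expect_true(length(unique(comp[got])) == 1)
  }
})

test_that("prioritization follows the component and tie-break rules", {
  # candidates {A,B,C,D}: A-B strongly correlated, C-D moderately, A-C not.
  # Components {A,B} and {C,D} tie on size; summed loading decides.
  cmat <- diag(4)
  rownames(cmat) <- colnames(cmat) <- c("A", "B", "C", "D")
  cmat["A", "B"] <- cmat["B", "A"] <- 0.9
  cmat["C", "D"] <- cmat["D", "C"] <- 0.5
  got <- metaprog:::largest_corr_component(cmat, 0.4, c(A = 1, B = 1,
                                                        C = 3, D = 3))
  expect_setequal(rownames(cmat)[got], c("C", "D"))
  got2 <- metaprog:::largest_corr_component(cmat, 0.4, c(A = 5, B = 5,
                                                         C = 1, D = 1))
  expect_setequal(rownames(cmat)[got2], c("A", "B"))
  # equal loadings too: lexicographic order decides
  got3 <- metaprog:::largest_corr_component(cmat, 0.4, c(A = 1, B = 1,
                                                         C = 1, D = 1))
  expect_setequal(rownames(cmat)[got3], c("A", "B"))
})

test_that("factor retention enforces the minimum prioritized-gene count", {
  spec <- small_spec(seed = 23, n_programs = 2)
  sim <- generate_mouse_cohorts(spec)
  filt <- filter_genes(malignant_cells(sim$counts), 0.01)
  fs <- run_nmf(filt, "A", 4, seed = 9)
  pr10 <- prioritize_factor_genes(fs, filt, z_thr = 1.5, corr_thr = 0.4,
                                  min_genes = 10)
  expect_true(all(lengths(pr10$prioritized_genes[pr10$retained]) >= 10))
  # raising the bar above every component size discards everything
  pr_huge <- prioritize_factor_genes(fs, filt, z_thr = 1.5, corr_thr = 0.4,
                                     min_genes = 1000)
  expect_false(any(pr_huge$retained))
  # fully correlated candidates form one component containing them all
  pr_all <- prioritize_factor_genes(fs, filt, z_thr = 1.5, corr_thr = -1.1,
                                    min_genes = 2)
  cand_counts <- sapply(seq_len(4), function(j) {
    z <- metaprog:::zscore_loadings(fs$loadings)[, j]
    sum(z > 1.5)
  })
  # factors with < 2 candidates cannot form a component at all
  expect_equal(lengths(pr_all$prioritized_genes),
               ifelse(cand_counts >= 2, cand_counts, 0),
               ignore_attr = TRUE)
})

test_that("planted programs are recovered by prioritized factor genes", {
  # default study conditions: 5 disjoint 40-gene programs, effect 6
  spec <- synthetic_spec(seed = 5)
  sim <- generate_mouse_cohorts(spec)
  filt <- filter_genes(malignant_cells(sim$counts), 0.01)
  prs <- list()
  for (ch in c("A", "B")) {
    fs <- prioritize_factor_genes(
      run_nmf(filt, ch, 30, seed = derive_seed(5, ch)), filt)
    prs <- c(prs, fs$prioritized_genes[fs$retained])
  }
  jac <- sapply(sim$truth$program_genes, function(tg) {
    max(sapply(prs, function(pg) {
      length(intersect(tg, pg)) / length(union(tg, pg))
    }))
  })
  expect_gte(sum(jac >= 0.5), 4)
})
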