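make_activity <- function(scores) {
  structure(list(scores = scores,
                 thresholds = apply(scores, 2, global_k1_threshold),
                 active = sweep(scores, 2,
                                apply(scores, 2, global_k1_threshold), ">"),
                 top_frac = 0.05), class = "activity_matrix")
}

test_that("factor activity correlation is Pearson with flagged constants", {
  s <- cbind(F1 = c(1, 2, 3, 4, 5), F2 = c(2, 4, 6, 8, 10),
             F3 = c(5, 4, 3, 2, 1), F4 = rep(0.5, 5),
             F5 = c(1, 3, 2, 5, 4))
  cc <- factor_activity_correlation(make_activity(s))
  expect_equal(diag(cc), rep(1, 5), ignore_attr = TRUE)
  expect_equal(cc["F1", "F2"], 1)
  expect_equal(cc["F1", "F3"], -1)
  # hand Pearson on 5 cells
  expect_equal(cc["F1", "F5"],
               sum((s[, 1] - 3) * (s[, 5] - 3)) /
                 sqrt(sum((s[, 1] - 3)^2) * sum((s[, 5] - 3)^2)))
  expect_equal(unname(cc["F4", c(1, 2, 3, 5)]), rep(0, 4))
  expect_true("F4" %in% attr(cc, "constant"))
  expect_equal(cc, t(cc), ignore_attr = TRUE)
})

test_that("identically-defined factors correlate at exactly 1", {
  spec <- small_spec(seed = 51)
  sim <- generate_mouse_cohorts(spec)
  cm <- subset_cells(sim$counts, cells = 1:50)
  genes <- sim$truth$program_genes[[1]]
  act <- score_programs(cm, gene_set_collection(
    list(Fa = genes, Fb = genes)), top_frac = 0.05, seed = 9)
  cc <- factor_activity_correlation(act)
  expect_equal(cc["Fa", "Fb"], 1)
})

test_that("silhouette-selected clustering recovers block structure", {
  set.seed(6)
  blocks <- rep(1:2, each = 5)
  corr <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.9, 0)) +
    matrix(runif(100, -0.02, 0.02), 10)
  corr <- (corr + t(corr)) / 2
  diag(corr) <- 1
  rownames(corr) <- colnames(corr) <- sprintf("F%d", 1:10)
  cl <- cluster_factors(corr, 2:8)
  expect_equal(cl$chosen_k, 2)
  expect_equal(length(unique(cl$labels[blocks == 1])), 1)
  expect_equal(length(unique(cl$labels[blocks == 2])), 1)
  # forced single candidate
  expect_equal(cluster_factors(corr, 2)$chosen_k, 2)
  # silhouette argmax agrees with independent re-evaluation
  d <- as.dist(pmax(1 - corr, 0))
  hc <- hclust(d, method = "average")
  manual <- sapply(2:8, function(k) {
    manual_mean_silhouette(cutree(hc, k), d)
  })
  expect_equal(cl$silhouettes$mean_silhouette, manual, tolerance = 1e-12)
  expect_equal(cl$chosen_k, (2:8)[which.max(manual)])
})

test_that("three noisy blocks select k = 3", {
  set.seed(12)
  blocks <- rep(1:3, times = c(4, 4, 5))
  corr <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.8, 0.05)) +
    matrix(runif(169, -0.05, 0.05), 13)
  corr <- (corr + t(corr)) / 2
  diag(corr) <- 1
  rownames(corr) <- colnames(corr) <- sprintf("F%d", 1:13)
  cl <- cluster_factors(corr, 2:10)
  expect_equal(cl$chosen_k, 3)
  expect_equal(adjusted_rand_index(cl$labels, blocks), 1)
})

test_that("degenerate all-equal correlations are rejected", {
  corr <- matrix(0.5, 4, 4)
  diag(corr) <- 1
  rownames(corr) <- colnames(corr) <- sprintf("F%d", 1:4)
  expect_error(cluster_factors(corr, 2:3), "undefined")
})

test_that("consensus gene rule implements the ceil(25%) arithmetic", {
  # 4 factors: presence in exactly 1 list suffices (1 >= ceil(0.25*4))
  lists4 <- list(c("a", "b"), c("b", "c"), c("b", "d"), c("e"))
  expect_true("a" %in% consensus_genes(lists4, 0.25))
  # 5 factors: 1 list is no longer enough (ceil(0.25*5) = 2)
  lists5 <- c(lists4, list(c("f")))
  cg5 <- consensus_genes(lists5, 0.25)
  expect_false("a" %in% cg5)
  expect_true("b" %in% cg5)
  # ordering: occurrence count desc, then gene id
  expect_equal(consensus_genes(list(c("z", "a"), c("z", "a"), c("z")), 0.25),
               c("z", "a"))
  # single factor: consensus is that factor's genes
  expect_setequal(consensus_genes(list(c("x", "y")), 0.25), c("x", "y"))
  # permutation invariance in factor order
  expect_setequal(consensus_genes(lists5, 0.25),
                  consensus_genes(rev(lists5), 0.25))
})

test_that("inactivity filter discards only programs quiet in every cohort", {
  mps <- list(
    list(id = "x", genes = "g", member_factors = list(),
         active_frac = c(A = 0.30, B = 0.02), total_active_frac = 0.16),
    list(id = "y", genes = "g", member_factors = list(),
         active_frac = c(A = 0.04, B = 0.06), total_active_frac = 0.05),
    list(id = "z", genes = "g", member_factors = list(),
         active_frac = c(A = 0.50, B = 0.40), total_active_frac = 0.45))
  kept <- drop_inactive(mps, 0.10, rule = "all")
  expect_equal(vapply(kept, `[[`, "", "id"), c("MP1", "MP2"))
  # relabeled by descending total activity: z (0.45) then x (0.16)
  expect_equal(vapply(kept, function(m) m$total_active_frac, 0),
               c(0.45, 0.16))
  # "any" reading drops the model-exclusive program too
  expect_length(drop_inactive(mps, 0.10, rule = "any"), 1)
  # zero threshold keeps everything
  expect_length(drop_inactive(mps, 1e-9, rule = "all"), 3)
})

test_that("assembly on a small planted cohort yields matching metaprograms", {
  # integration smoke at reduced scale; recovery strength at the default
  # study conditions is asserted by the end-to-end recovery tests
  spec <- small_spec(seed = 57, n_programs = 3)
  sim <- generate_mouse_cohorts(spec)
  cfg <- mp_config(n_factors = 12, n_stability_runs = 1, master_seed = 57)
  filt <- filter_genes(malignant_cells(sim$counts), cfg$min_gene_cell_frac)
  fsets <- lapply(c("A", "B"), function(ch) {
    prioritize_factor_genes(run_nmf(filt, ch, 12, derive_seed(57, ch)), filt)
  })
  asm <- assemble_metaprograms(fsets, filt, cfg, seed = 57)
  expect_gte(length(asm$metaprograms), 1)
  truth <- sim$truth$program_genes
  jac <- sapply(truth, function(tg) {
    max(sapply(asm$metaprograms, function(mp) {
      length(intersect(tg, mp$genes)) / length(union(tg, mp$genes))
    }))
  })
  expect_gte(sum(jac >= 0.3), 1)
  for (mp in asm$metaprograms) {
    expect_true(all(mp$active_frac >= 0 & mp$active_frac <= 1))
    expect_gt(length(mp$genes), 0)
    expect_true(all(vapply(mp$member_factors, function(m)
      fsets[[match(m$cohort, c("A", "B"))]]$retained[m$factor], TRUE)))
  }
})
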