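# Independent oracles and small fixture builders shared across tests.

# Brute-force recovery-curve integration: walk the ranking, accumulate the
# cumulative count of set members at each of the top m ranks, and normalize
# by the best attainable curve. Independent of the closed form used by
# rank_auc().
brute_force_recovery_auc <- function(expr, gene_set, top_frac, seed) {
  G <- length(expr)
  set.seed(seed)
  pri <- numeric(G)
  pri[order(names(expr))] <- sample.int(G)
  ordering <- names(expr)[order(-expr, pri)]
  gene_set <- intersect(gene_set, names(expr))
  s <- length(gene_set)
  m <- ceiling(top_frac * G)
  curve <- numeric(m)
  hits <- 0
  for (r in seq_len(m)) {
    if (ordering[r] %in% gene_set) hits <- hits + 1
    curve[r] <- hits
  }
  best <- pmin(seq_len(m), s)
  sum(curve) / sum(best)
}

# Union-find connected components on an edge list over n vertices.
union_find_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1])
      b <- find(edges[e, 2])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, 0L)
}

# Exhaustive sign-flip enumeration of the one-sided signed-rank test
# P(W >= w_obs) over all 2^n sign patterns of the observed absolute ranks.
enumerate_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  total <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(r[signs == 1]) >= w_obs) total <- total + 1L
  }
  total / 2^n
}

# Mean silhouette width computed from first principles.
manual_mean_silhouette <- function(labels, dmat) {
  dmat <- as.matrix(dmat)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) {
      s[i] <- 0
      next
    }
    a <- mean(dmat[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(dmat[i, labels == g])
    }, 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# Hand log-rank statistic: sum over distinct event times of observed minus
# expected events in group 1, hypergeometric variance, grouped ties.
manual_logrank_chi2 <- function(time, event, group) {
  g1 <- group == levels(factor(group))[1]
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# All permutations of 1..n (n small); rows are permutations.
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Tiny annotated count matrix with two cohorts.
tiny_cm <- function(counts = matrix(c(3, 0, 1, 0, 2, 5, 4, 0), 2),
                    cohort = c("A", "A", "B", "B")) {
  n <- ncol(counts)
  count_matrix(counts, sprintf("g%d", seq_len(nrow(counts))),
               sprintf("c%d", seq_len(n)), cohort,
               sample_id = paste0("t", rep(1, n)),
               malignant = rep(TRUE, n))
}

# Small synthetic spec used by module tests (kept quick on purpose).
small_spec <- function(seed = 11, n_programs = 3, effect = 6) {
  synthetic_spec(n_genes = 500, n_cells_per_cohort = 250,
                 programs = default_planted_programs(500, n_programs, 40,
                                                     effect),
                 n_tumors_human = 8, n_cells_per_tumor_human = 30,
                 seed = seed)
}
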