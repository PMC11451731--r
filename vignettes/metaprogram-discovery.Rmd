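---
title: "Metaprogram discovery: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaprogram discovery: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical procedure implemented by `metaprog`,
the tunable parameters and the reasoning behind their defaults, what the
synthetic-cohort generator does and does not emulate, and the numerical and
design choices made where the procedure admitted more than one reasonable
reading.

## The problem

Malignant cells within and across tumors re-use a limited repertoire of
gene-expression programs. Matrix factorization of single-cell expression
recovers candidate programs per tumor or model, but individual NMF factors
are noisy and non-unique: re-running the optimization from a different
initialization yields different factors. The pipeline therefore treats a
*metaprogram* — a cluster of factors recurring across cohorts, summarized by
a consensus gene list — as the unit of biology, and stabilizes the whole
procedure by repeating it and selecting a typical repeat.

## The procedure

### Input and normalization

The input is a sparse gene × cell matrix of non-negative integer counts with
per-cell cohort, sample, and malignant annotations (`count_matrix`). Genes
are filtered to those detected in at least `ceil(min_gene_cell_frac × n)` of
the pooled malignant cells (default 1%, inclusive: a gene in exactly 1% of
cells is kept). NMF runs on `log1p(counts-per-10k)` per cell. The scale of
the factorized matrix was an open choice; log counts-per-10k is the standard
normalization for program discovery on UMI data and is non-negative by
construction, which the factorization requires. Rank-AUC activity scoring is
rank-based and therefore invariant to this choice.

### Factorization and gene prioritization

Each cohort's malignant cells are factorized separately at rank
`n_factors` (default 30) by HALS updates minimizing the Frobenius error,
with no regularization, from a seeded uniform random initialization.
Convergence is declared when the relative change of the relative
reconstruction error falls below 1e-5, or after 500 sweeps — tolerances
chosen to make 100 repeats practical on one CPU; the elbow scan
(`elbow_rank_scan`) reports per-rank errors but deliberately performs no
automatic rank selection.

Genes are prioritized per factor in two steps. First, each gene's loading is
z-scored *across the factor axis* (the literal reading of standardizing "a
gene's loadings across all factors"); genes with `z > 1.5` are the factor's
candidates. A gene whose loadings are identical in every factor carries no
factor-specific information and gets z = 0 everywhere. Second, a
co-expression graph is built **among the candidates only** — the graph is
scoped to the factor, not the whole transcriptome — with edges where the
Spearman correlation of expression across the cohort's own cells exceeds
0.4. The prioritized list is the largest connected component; ties on
component size break by summed loading, then by lexicographic gene order, so
the output is deterministic. Factors with fewer than 10 prioritized genes
are discarded.

### Activity scoring

The activity of a gene list in a cell is the area under the recovery curve
of list members within the top `ceil(auc_top_frac × G)` expression ranks of
that cell, normalized by the maximum attainable area; `auc_top_frac`
defaults to 0.05, the convention of rank-AUC scoring tools. Expression ties
— ubiquitous in sparse counts — are broken by a per-cell seeded random
permutation whose priorities are assigned in lexicographic gene order;
breaking ties by storage index instead would bias scores toward genes that
happen to sit early in the matrix, and would make scores depend on row
order. A cell is *active* for a program when its score strictly exceeds the
program's global threshold, defined as mean + 1 sd of a normal fit to all
cells' scores ("global, k = 1"). The upstream tool names but does not define
this threshold; mean + 1·sd of the global score distribution is the
operative definition here, stated openly rather than guessed further. Under
roughly normal scores it calls ~16% of cells active; for degenerate
constant scores the threshold equals the mean and no cell is active.

### Metaprogram assembly

Retained factors from both cohorts are scored on the pooled cells, their
activity vectors correlated (Pearson; constant vectors get correlation 0 and
are flagged), and hierarchically clustered on distance 1 − r with average
linkage — the conventional linkage for correlation distances. The cluster
count is chosen by maximum mean silhouette over `2..min(15, n_factors − 1)`,
ties to the smaller k. Each cluster's consensus keeps genes present in at
least `ceil(0.25 × members)` of the member factors' lists. Metaprograms
active in fewer than 10% of cells *in every cohort* are discarded: the
discard rule's "each model" could also be read as "any model", but a program
active in only one model is a reportable model-enriched program, so the
conservative reading is the default and the other is available as
`inactive_rule = "any"`. Survivors are relabeled MP1..MPm by descending
total active fraction, since the original numbering of metaprograms is
arbitrary and a deterministic order is needed.

### Stability selection

The discovery procedure is repeated `n_stability_runs` times (default 100)
with independently derived seeds. Each repeat is scored by the auROC of an
L2-regularized logistic regression (penalty strength 1, i.e. ridge with
λ = 1/n) separating the two cohorts from per-cell metaprogram activities,
under stratified 5-fold cross-validation; the auROC is computed once on the
pooled out-of-fold probabilities rather than averaged over folds, which has
lower variance at these sample sizes. Both the NMF initialization and the
fold assignment are re-randomized per repeat. The repeat with the median
auROC is selected; with an even number of repeats the lower of the two
middle values is taken, because an actual repeat (not an interpolated score)
must be selected, and ties resolve to the smallest run index. Repeats
producing zero metaprograms are excluded from the median rather than scored
0.5: a failed decomposition is not a valid candidate catalogue. A
one-feature catalogue is fit by unpenalized logistic regression because the
ridge solver requires at least two columns; with a single feature the
decision function is monotone in it either way, so the auROC is unaffected.

### Cell states, cross-cohort correspondence, survival

Metaprogram activities are z-scored per program over all pooled cells with
the sample (n−1) standard deviation — the published z formula does not fix
the denominator, and the sample sd matches common implementations. Cells are
joined into a k = 30 nearest-neighbor graph under the Mahalanobis metric
(the covariance of the z-scores, ridge-regularized by 1e-6·trace(Σ)/p when
ill-conditioned, since metaprogram activities can be near-collinear), the
union of directed edges taken as an undirected, unweighted graph — the
published description does not state an edge weighting, so unweighted
modularity is used. Louvain at resolution 0.4 runs 100 times with distinct
seeds and the labeling with the highest mean silhouette under the same
Mahalanobis distances is kept. UMAP embeddings are computed only for
visualization and never used in clustering.

Cross-cohort correspondence scores two catalogues on the same cells (mouse
gene lists pass through the homolog map first), computes Spearman ρ per
program pair within each tumor of at least 20 cells — small biopsies give
unstable ranks; the published analysis used a 50-cell floor for a different
cell compartment, and 20 is exposed as `min_cells_per_tumor` — and calls a
pair shared within a cohort when the tumor-wise ρ vector is significantly
above 0.2 by a one-sided Wilcoxon signed-rank test (the test is applied to
the tumor-wise vector, not to the retained median, which is the literal
reading of the published sentence). Zeros are dropped; for n ≤ 25 the
p-value is exact, computed by dynamic programming over signed midranks so it
remains valid under ties; beyond that a normal approximation with continuity
and tie correction is used. No multiple-testing correction is applied across
pairs, matching the published procedure; Benjamini–Hochberg is available but
off by default. One-to-many homolog relations resolve to the alphabetically
first target present in the data — the published analysis does not state its
rule, and a deterministic tie-break is required for reproducibility.

Outcome association sums counts per sample, normalizes as
`log2(CPM + 0.001)`, z-scores signature genes across samples (sample sd),
averages them per sample, splits samples at the median — the median itself
goes to the High group, exactly as printed — and compares progression-free
survival by the standard log-rank test with grouped handling of tied event
times.

## Randomness and reproducibility

All randomness flows from a single `master_seed` through
`derive_seed(master_seed, stage, index)`, a polynomial hash of the stage
name combined with the run index modulo a prime below 2^31. Repeats are
therefore independent of execution order, and re-running any pipeline stage
on identical inputs produces byte-identical outputs (checked via manifest
hashes).

## The synthetic generator

`generate_mouse_cohorts()` draws per-gene baseline rates from a Gamma
distribution, per-cell program activity as Bernoulli with cohort-specific
probabilities, and counts as Poisson around
`library_size × softnorm(baseline × active-program effects)`, with
log-normal library sizes. The soft normalization rescales per-cell rates to
sum to one before multiplying by library size, so planted effects change
composition, not sequencing depth. Poisson emission is the simplest model
satisfying the pipeline's assumptions; a negative-binomial `dispersion`
parameter is available for robustness experiments. The human-like cohort
plants only the programs marked shared, through homolog identifiers, with
per-tumor activation probabilities jittered around the cohort level (Beta,
concentration 6) so that pseudobulk scores genuinely vary between tumors —
without this the survival link would act on pure sampling noise.
Progression-free survival is exponential with log-hazard equal to the sum of
`hazard_coef × standardized per-tumor mean program dose`, censored by an
independent Uniform(0, 2 × mean PFS) time, which keeps roughly 30–50% of
tumors as events without extra parameters.

The generator deliberately omits doublets, ambient RNA, batch effects, and
cell-cycle structure. Passing the validation suite therefore demonstrates
that the pipeline recovers planted compositional programs under clean
Poisson sampling — it does not demonstrate robustness to the technical
artifacts of real droplet data.

## Validation design and problem sizes

The package validates itself at two scales. Module tests use small cohorts
(300–500 genes, 150–300 cells per cohort, ranks 5–12) for speed and check
exact properties: rank-AUC against brute-force recovery-curve integration,
component selection against union-find, the exact Wilcoxon against full
sign enumeration, silhouette selection against first-principles
recomputation, and the log-rank statistic against a hand hypergeometric
calculation. End-to-end recovery runs at the generator's default study
conditions — 2000 genes, five disjoint 40-gene programs at effect 6 (two
cohort-exclusive), 600 cells per cohort, 10 stability repeats — where at
least 4 of 5 planted programs are expected to match a discovered
metaprogram at gene Jaccard ≥ 0.5, with cohort-separation auROC above 0.9,
and an auROC near 0.5 when activation probabilities are equalized. The
cross-cohort stage is validated on 50 power and 200 null simulated human
cohorts (200 genes, 8 tumors × 30 cells), and the survival stage on 1000
null splits (40 patients) plus 60 hazard-linked cohorts (300 genes, 16
tumors × 40 cells). These sizes are the package's own validation choices,
selected to give stable rates on a single CPU.

## Known limitations

- NMF rank is a fixed input; the elbow scan assists a manual choice but no
  automatic selection is attempted.
- The global activity threshold is a simple mean + 1 sd fit; alternative
  threshold families (density minima, mixture-based cutoffs) are not
  implemented.
- The stability classifier assumes exactly two cohorts.
- Cross-cohort calling tests each pair marginally; the optional BH
  correction treats pairs within a cohort as a family, nothing more.
- The survival stage implements only the published median-split log-rank
  comparison — no proportional-hazards regression or covariate adjustment.
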