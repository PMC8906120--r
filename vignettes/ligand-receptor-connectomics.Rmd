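---
title: "Ligand–receptor connectomics: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand–receptor connectomics: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrnet)
```

## The model

`lrnet` treats a clustered single-cell RNA-seq dataset as a multicellular
system whose nodes are cell-type clusters. Given a reference table of known
ligand→receptor mechanisms, the package enumerates every directed
celltype–ligand–receptor–celltype edge: cluster *i* can signal to cluster *j*
through mechanism *k* = (L, R) if *i* expresses the ligand L and *j* expresses
the receptor R. Because a cluster blends all cells assigned to it, every
node-level quantity is a per-cluster summary; parcellation quality is an
input assumption, not something the package checks.

Each edge (i, j, k) carries two complementary weights:

* **weight_norm** = `mean_norm(i, L) * mean_norm(j, R)`, the product of the
  clusters' mean normalized expressions. It measures raw connectivity and is
  the natural scale for comparing the same edge across two conditions.
* **weight_scale** = `(z(i, L) + z(j, R)) / 2`, the mean of the system-wide
  gene z-scores of the ligand in the source and the receptor in the target.
  It measures specificity: how much more than the system average these two
  clusters use this mechanism. It is the default for within-system
  exploration and for centrality, because a ubiquitous, highly expressed
  ligand should not drown out a rare but dedicated sender.

A consequence of the z-score construction worth knowing: a gene expressed
nowhere has zero variance and contributes z = 0 everywhere, so an entirely
silent mechanism still has `weight_scale = 0 + partner/2` rather than being
absent. The expression-fraction and significance gates remove such edges in
practice.

## Node statistics and their estimation

`cluster_profile()` reduces the cells × genes matrix to four cluster × gene
matrices:

* `mean_norm` — mean of library-size-normalized, log1p-transformed
  expression. `normalize_cells()` implements the standard recipe (counts
  scaled to a fixed per-cell total, default 10,000, then `log(1 + x)`).
  Data normalized upstream by another method can be passed through with
  `is_normalized = TRUE`.
* `mean_scaled` — mean of gene-wise z-scores taken across **all retained
  cells**, not within clusters; this is what makes `weight_scale` reflect the
  topology of the whole system. Z-scores use the sample standard deviation
  (n − 1), matching the dominant single-cell ecosystem, and clipping is off
  by default because truncation changes `weight_scale`; a `clip` argument is
  available for workflows that want display-style truncation.
* `frac_expr` — the fraction of cells with value > 0, the simplest reading of
  "expressed".
* `pval` — the two-sided one-vs-rest Wilcoxon rank-sum p-value of the gene in
  the cluster against all other retained cells. Raw p-values are what the
  default gates use; a Benjamini–Hochberg column (`pval_adj`, adjusted within
  each cluster) is emitted alongside for users who prefer it.

Clusters smaller than `min_cells_per_ident` are removed before anything is
computed, including z-scaling. The library default is 0 (keep everything);
75 is a sensible choice for noisy tissue atlases and is what the
command-line demo configuration uses.

### Wilcoxon details

The rank-sum test is the package's only inferential primitive, so its
numerical contract is pinned precisely:

* pooled n ≤ 25 and no ties: the classical exact null distribution
  (`stats::pwilcox`).
* pooled n ≤ 25 with ties (and a feasible number of assignments): exhaustive
  enumeration of the conditional permutation distribution of the midrank
  sum; the two-sided p-value is the null probability of a deviation from the
  mean rank sum at least as large as observed. For tie-free data this
  coincides with the classical exact test. The canonical worked case —
  (0,0,0) vs (2,2,2) — gives p = 2/20 = 0.1.
* otherwise: the normal approximation with tie correction and continuity
  correction, identical to `stats::wilcox.test(exact = FALSE,
  correct = TRUE)`.

Degenerate inputs (an empty group, zero pooled variance) return p = 1.

## Edge gates

`filter_connectome()` implements the single-system recipe: keep an edge when
the ligand and the receptor are each expressed in **more than** `min_frac`
of their own cluster (default 0.1) and each have a one-vs-rest p-value
**below** `max_p` (default 0.05). Both inequalities are strict, so a
fraction exactly at 0.1 or a p-value exactly at 0.05 is dropped — the
boundary behavior is pinned by tests. The ligand is always judged in the
source cluster and the receptor in the target cluster; that is the only
coherent reading of "their respective clusters". An optional z-score gate
(`min_z`, both genes strictly above) reproduces the stricter
specificity-thresholded views, and identity filters (sources, targets,
mechanisms, families) compose with the statistical gates.

## Centrality

For any edge subset (typically one signaling family),
`aggregate_adjacency()` sums the chosen weight over mechanisms into a
cluster × cluster matrix, and two metric families are computed:

* cumulative outgoing/incoming edgeweight per node, as a fraction of the
  subset's total weight;
* Kleinberg hub and authority scores, by the mutually reinforcing power
  iteration (authority ← Aᵀh, hub ← Aa) from a uniform start, renormalized
  to maximum 1 each round, declared converged when successive iterates
  differ by less than `tol` (default 1e-10) in max-norm. The iteration is
  deterministic, so no seed is involved; non-convergence is an error that
  reports the residual. Tests verify the result against dense
  eigendecompositions of AAᵀ and AᵀA.

HITS needs non-negative weights while `weight_scale` may be negative. The
default policy floors negative weights at zero during aggregation; on
filtered networks surviving weights are positive in practice, so flooring is
the least surprising choice. `shift` (translate so the minimum is zero) and
`drop` (remove negative edges) are available for sensitivity analyses — the
choice is this package's documented convention, not something the method
itself prescribes. Normalizing hub/authority to max 1 (rather than unit
norm) keeps dot-size plots interpretable; tests compare directions, not
scales. When a family's graph has several weakly connected components the
dominant component determines the scores and a warning is emitted.

`group_by_dominant_receiver()` reduces each family to the class of its
top-authority cluster, with deterministic tie-breaks (incoming weight
fraction, then lexicographic cluster name), reproducing the family-grouping
step of single-tissue portraits. `compare_centrality()` stacks per-system
tables without trying to align node sets, because disparate systems need not
share cell types.

## Differential connectomics

`differential_connectome()` aligns two connectomes built against the same
database on their shared cluster labels (no fuzzy matching — label
harmonization is the caller's job) and computes, per edge,

```
ligand_log2fc   = log2((ligand_norm_test + eps) / (ligand_norm_ctrl + eps))
receptor_log2fc = likewise, in the target cluster
perturbation_score = |ligand_log2fc| * |receptor_log2fc|
```

with pseudocount `eps = 0.01` by default, because the raw ratio is undefined
when a mean is zero. Two zero means give a ratio of exactly 1 and hence a
fold change of exactly 0. The score is zero iff either fold change is zero,
grows with change on both sides regardless of direction, and is unchanged
when the two conditions are swapped.

The sign pattern classifies each edge: UP_UP ("activated"), DOWN_DOWN
("deactivated"), UP_DOWN ("ligand pressure"), DOWN_UP ("ligand starvation").
Edges with a fold change of exactly zero get a fifth label, `NULL`, so that
unchanged edges cannot contaminate the four perturbation classes; the
eight-way scheme for single-sided changes is deliberately not modeled.

Significance across conditions comes from `cross_condition_wilcoxon()`,
which compares each cluster's per-cell normalized values between conditions
gene by gene — per cell, not per cluster mean. `filter_differential()` then
keeps edges with both cross-condition p-values strictly below `max_p`,
ligand and receptor each expressed in more than `min_frac_either` of their
cluster **in either condition** (a gene may be silent before treatment and
active after it), and a perturbation score at least `min_score`. The score
threshold is inclusive (it is a floor, "minimum score of 2" style) while the
p and fraction gates are strict, mirroring the asymmetry in how such
thresholds are conventionally phrased.

## Vectortype embedding

Each (source, target) pair — a *vectortype* — can be viewed as a feature
vector of its mechanism weights. `build_vectortype_matrix()` pivots the edge
list into that matrix (filtered-out edges contribute 0);
`embed_vectortypes()` L2-normalizes rows, builds a symmetric k-nearest-
neighbor graph under Euclidean distance (ties broken by row index), assigns
vectortype clusters by Louvain community detection on that graph, and lays
the graph out in 2D with a force-directed algorithm. The kNN graph and the
communities are deterministic given the data; only the 2D coordinates depend
on the seed, which is why the package's guarantees (and tests) are stated on
graph structure rather than coordinates. Neighbor count, weight choice and
seed are all exposed because no canonical recipe exists for this view; the
defaults (k = 10, `weight_scale`) favor specificity structure.

## The synthetic-data generator

`synthetic_spec()` / `generate_synthetic()` produce the cluster-structured
counts every end-to-end test runs on: negative-binomial counts (variance
μ + φμ², default dispersion φ = 0.5) with independent Bernoulli dropout
(default 20%), planted cluster-specific ligand/receptor markers, and a
matching ligand–receptor database containing the planted pairs (one family
each) plus decoy mechanisms drawn among background genes (default 10).
`generate_condition_pair()` adds multiplicative (cluster, gene) effects to a
test condition for differential analyses. Generation is a pure function of
the spec; the seed fixes everything.

The reference conditions are 4 clusters × 200 cells, planted effects of
4-fold, and 1000 background genes at mean 2 — roughly 2,000-count
libraries. The background transcriptome is deliberately large enough that no
single gene is more than a fraction of a percent of a cell's library: with a
toy-sized transcriptome (tens of genes), a 4-fold change in one gene shifts
every cell's total by tens of percent and library-size normalization then
manufactures systematic, statistically significant fold changes in every
other gene — an artifact of the simulation, not a property of real data,
and one that this generator is sized to avoid.

What the generator does *not* emulate: mean–variance trends across genes,
expression-dependent dropout, batch effects, doublets, ambient RNA, or
continuous cell states straddling cluster boundaries. Passing tests
therefore demonstrate that the statistics and gates behave as specified
under clean cluster structure and overdispersed counts; they do not certify
performance on data whose parcellation or normalization is itself
questionable.

## Validation design

The package's guarantees are checked three ways (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`):

* **Oracles** — stored edgeweights and perturbation scores against one-line
  recomputations; rank-sum p-values against exhaustive permutation
  enumeration for every pooled configuration up to n = 8; HITS against dense
  eigendecompositions on random graphs.
* **Planted-signal recovery** — on the reference conditions, planted edges
  must top their mechanism's `weight_scale` ranking, survive the default
  gates across simulation replicates, and (in the differential mode) come
  out UP_UP with the top perturbation score of the gated network; the
  effect-size-1 null must pass almost no decoy edges through the
  fraction-and-significance conjunction.
* **Determinism and round-trips** — MTX/CSV readers and writers are
  lossless, and identical configurations produce byte-identical outputs.

Problem sizes were chosen so that the whole suite runs comfortably on a
laptop-class single core: 20 replicates of the 800-cell reference
simulation for each recovery property, 100 random graphs for the centrality
oracle, and exhaustive Wilcoxon enumeration only where the configuration
count is small.

## Known limitations

* Mechanisms are strictly pairwise; multi-subunit receptor complexes are not
  represented.
* Mean-wise aggregation hides within-cluster heterogeneity by design.
* No spatial proximity or downstream transduction likelihood enters the
  edgeweights.
* Gene-symbol matching is exact and case-sensitive by default; `case_fold`
  upper-cases symbols for cross-species use but performs no alias
  resolution.
* The family labels shipped in the bundled example table are illustrative;
  serious analyses should supply a curated reference table.
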