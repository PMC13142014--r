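---
title: "Phylogeny-informed random forests: model, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-informed random forests: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirf)
```

## The problem

Microbiome feature tables (OTUs or amplicon sequence variants by sample) are
high-dimensional, sparse, zero-inflated, and heavily skewed, and usually ship
with a phylogenetic tree relating the features. Random forests handle the
distributional pathologies well, but treat features as exchangeable. The idea
implemented here is to let the phylogeny shape the forest's *feature
sampling*: features that are evolutionarily close tend to be functionally
related, so importance can be assessed *locally*, within phylogenetic
neighbourhoods, and then recombined into a community-level sampling
distribution for the final forest. The hoped-for effect is a balance between
two failure modes of importance-weighted forests — globally competitive
weighting correlates the trees (all trees lean on the same few winners),
while uniform sampling wastes splits on uninformative features.

## The procedure

Given an abundance table $X \in \mathbb{R}^{n \times p}$ (rows sum to one
after normalization), an outcome $y$ (binary or numeric), and a rooted tree
whose leaves are the $p$ features:

1. **Phylogenetic clusters.** Compute the cophenetic (patristic) distance
   between every pair of leaves — the total branch length of the path
   through their most recent common ancestor. Partition the features with
   PAM (partitioning around medoids), choosing the number of clusters
   $k_{\text{phylo}}$ that maximizes the average silhouette width over the
   range 2–10. Clusters are mutually exclusive and exhaustive; cluster $k$
   has $q_k$ features.

2. **Localized importance.** Within each cluster, train random forests
   restricted to that cluster's $q_k$ features — one forest per candidate
   mtry value in $\{\lceil q_k/10 \rceil, \lceil \sqrt{q_k} \rceil,
   \lceil \log_2 q_k \rceil\}$ (clamped to $[1, q_k]$, deduplicated) — and
   average the out-of-bag permutation importance scores $s_j$ across the
   candidates.

3. **Community-level probabilities.** Clip negative scores to zero
   (elimination), normalize within each cluster,
   $v_j = s_j / \sum_{r \in C_k} s_r$, and scale by the cluster's size
   share: $w_j = v_j \cdot q_k / p$. The $w_j$ sum to one; each cluster
   holds exactly its size share of the total mass, so no cluster can crowd
   out another. The count of non-zero entries is $p'$.

4. **Final forest.** Tune the global mtry over
   $\{\lceil p'/10 \rceil, \lceil \sqrt{p'} \rceil, \lceil \log_2 p'
   \rceil\}$ by out-of-bag error, then grow the final forest in which each
   node's mtry candidate features are drawn without replacement with
   probability proportional to $w$.

Two boundary cases anchor the construction: fully disjoint clusters
($k = p$) give $w_j = 1/p$ exactly — the standard random forest — and a
single cluster ($k = 1$) gives the clipped, globally normalized importance
vector — globalized feature weighting. The package exposes all three as
`clustering = "phylo"`, `"disjoint"`, `"single"` and compares them under
shared cross-validation folds in `compare_variants()`.

## Parameters that matter

* `n_trees` (default 10,000): trees in the final, OOB-tuned forest. The
  large default stabilizes OOB comparisons on real tables; the package's
  own simulations and tests use 60–500 trees, which keeps every suite run
  in minutes at the simulated problem sizes.
* `n_trees_cluster` (default 1,000): trees per cluster-level importance
  forest. Importance estimates — not predictions — are the product of this
  stage, so it can be smaller than the final forest.
* `n_permutations` (default 1): permutations per tree and feature when
  scoring importance. One permutation per tree's OOB set is the
  conventional default; raising it smooths cluster-level scores.
* `k_range` (default `c(2, 10)`): the silhouette search range. The fixed
  upper end assumes $p \gg 10$; when $p \le 10$ the range is capped at
  $p - 1$ because at $k = p$ every feature is a singleton and the
  silhouette degenerates. Whether wider ranges help is untested here; the
  range is a plain knob.
* `min_node_size` (default 1 for classification, 5 for regression): nodes
  at or below this size become leaves. These are the customary defaults of
  fast forest implementations.
* Preprocessing thresholds: samples are kept only with **more than** 2,000
  total reads, features only with mean relative abundance **strictly
  greater than** 0.00001 (both exclusive bounds, both configurable). Rows
  are renormalized over the retained features.

### The middle mtry candidate

The candidate set is stated as $\lceil q/10 \rceil, \lceil q \rceil,
\lceil \log_2 q \rceil$ in the method's description; a literal
$\lceil q \rceil$ means "use every feature", which collapses the candidate
set and contradicts how forests are normally tuned. The package reads the
middle candidate as $\lceil \sqrt{q} \rceil$ — the canonical default — and
exposes the literal reading as `mtry_middle = "literal"` for anyone who
wants the other interpretation.

## Numerical and tie-breaking choices

Determinism was a design goal: every stage is exactly reproducible from one
seed, which expands into per-stage, per-tree seeds (the forest engine uses
its own counter-based RNG, so results do not depend on R's RNG state).

* Split thresholds are midpoints between adjacent distinct observed values;
  ties in impurity decrease break toward the lower feature index, then the
  lower threshold. Splits with decrease below $10^{-12}$ are not accepted.
* Majority votes and nearest-medoid assignments break ties toward the
  lexicographically smaller class label / lower index.
* PAM is the classical deterministic BUILD + SWAP algorithm (via the
  reference implementation in the `cluster` package); silhouette ties
  across $k$ break toward the smaller $k$. Singleton clusters contribute a
  silhouette of 0 (Rousseeuw's convention).
* A *degenerate* cluster — all clipped scores zero — contributes zero mass,
  and the full vector is renormalized at the end, preserving the relative
  masses of the surviving clusters. The unit-sum constraint only holds
  automatically when every cluster normalizes, and the $0/0$ case needs a
  convention; this one keeps the cluster-size logic intact. If *every*
  cluster is degenerate the vector falls back to uniform with a warning.
* Trees lacking branch lengths are rejected rather than defaulted: a
  missing length would silently distort the metric. Unrooted inputs and
  polytomies are fine — path-length distances do not depend on rooting.
* Features in the table but absent from the tree are an error by default
  (`tree_missing = "warn"` drops them instead); there is no principled
  imputation for a feature with no phylogenetic position.
* Classification is binary only; multiclass input is rejected with a clear
  message rather than silently handled.
* Model files are JSON with doubles written at 17 significant digits, so a
  stored model reproduces predictions bit-for-bit after reloading.

## The synthetic generator

`simulate_dataset()` emulates the regime the method targets: a pure-birth
(Yule) tree with i.i.d. exponential branch lengths; per-cell log-normal
abundances (`meanlog = 0`, `sdlog = 2`, heavy right skew) Bernoulli-masked
to zero with probability 0.7; row-normalized profiles scaled by per-sample
library sizes uniform on [5,000, 50,000] and rounded to counts; and an
outcome driven by the *summed relative abundance of one clade* (the clade
whose leaf count is closest to 25% of the features), standardized, with a
log-odds or linear slope of 5 per standard deviation. Defaults: 120 samples
by 40 features. A `signal_mode = "scattered"` switch draws the same number
of signal features at random — the no-advantage regime for phylogeny-aware
weighting.

What it does *not* emulate: compositional correlation structure beyond the
normalization itself, batch effects, taxon-specific detection biases,
Dirichlet-multinomial overdispersion, or real studies' margins. Passing the
simulation-based tests therefore shows the machinery behaves as constructed
— recovery of planted clades, correct boundary reductions, calibrated null
behaviour — not that the method wins on any particular real dataset.

## What the package's own simulations show

Two honest findings from the built-in studies (recomputed by
`scripts/acceptance.R` and the test suite on every run):

* **Mass recovery is bounded by design.** Because each cluster's total mass
  is pinned to $q_k/p$, a clade carrying all the signal attracts *more than
  its size share* of selection mass (observed in ≥ 9/10 seeded replicates)
  but cannot exceed its share by much unless clustering happens to straddle
  the clade or whole noise clusters are eliminated. Expecting a 25% clade
  to absorb most of the total mass misreads the construction.
* **At small $p$, localized weighting can lose to uniform sampling.** In
  the 40-feature simulations the estimated within-cluster importances are
  dominated by chance correlations (roughly 100 training samples), so the
  weighted forest concentrates on features that do not generalize, and its
  cross-validated error trails the plain uniform forest. Weighting is not
  hopeless in this regime — upweighting the *true* clade does help — but
  estimated localized importance is too noisy to find it at this scale. The
  method's reported strengths come from tables with hundreds to thousands
  of features, where elimination and weighting operate on much more mass.
  `compare_variants()` reports all three variants side by side so this
  comparison is always visible rather than assumed.

## Problem sizes used by the suites

Unit tests run on 15–60 samples × 12–20 features with 25–150 trees; the
acceptance checks use the generator defaults (120 × 40) with 100–300 trees,
200 PAM instances of 4–8 leaves against exhaustive enumeration, 100 random
trees of up to 50 leaves against a brute-force path-sum oracle, and 20
paired cross-validation replicates. These sizes are the package's choice of
simulation scale; all thresholds quoted above refer to them.

## Known limitations

* Binary classification and univariate regression only; no survival
  outcomes, covariate adjustment, or batch correction (apply an external
  correction first if needed).
* The silhouette range 2–10 is inherited convention, not an optimum.
* PAM is a local optimizer: on small instances it reaches the global
  2-medoid optimum ~98% of the time in our checks, and its rare misses are
  genuine swap-local optima a few percent above the optimum.
* Cluster-level forests default to 1,000 trees; the "right" number is
  unstated in the method's description and is exposed as a knob.
* Importance-driven weights inherit all the known biases of permutation
  importance under correlated features; within-clade correlation is exactly
  the situation here, so per-feature scores inside a signal clade split
  credit among relatives.
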