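---
title: "Rank-based algorithm selection for protein–ligand docking portfolios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based algorithm selection for protein–ligand docking portfolios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockselect)
```

## The problem

Stochastic docking solvers are not uniformly good. AutoDock's Lamarckian
Genetic Algorithm (LGA) behaves differently depending on its population
size, mutation rate, energy-window size and local searcher, and no single
parameterisation dominates across a ligand library: the configuration that
finds the lowest binding energy for one ligand is routinely beaten on
another. Per-instance **algorithm selection** (AS) exploits that
complementarity: given a portfolio of solver configurations and cheap
per-ligand features, pick the configuration expected to dock *this* ligand
best.

`dockselect` implements the full pipeline around a collaborative-filtering
selector in the ALORS style: instances play the role of users, algorithms
the role of items, and the training signal is the instance-by-algorithm
**rank matrix** rather than raw energies. The canonical portfolio is the
28-entry LGA grid — populations {50, 150, 200} × mutation rates
{0.02, 0.5, 0.8} × windows {10, 30, 50} with the pseudo-Solis–Wets local
searcher (A1–A27), plus the default parameterisation with the classical
Solis–Wets searcher (A28); `build_portfolio()` emits it.

## From docking runs to rank data

Each (ligand, configuration) pair is docked repeatedly (50 runs in the
reference protocol); `parse_dlg()` harvests one estimated free energy of
binding (kcal/mol, lower is better) per run from AutoDock DLG logs, and
`aggregate_runs()` collapses the runs either by their mean (**AVG**, the
expected behaviour of a stochastic solver) or their minimum (**BEST**, the
strongest pose found). The two modes answer different questions — AVG
rewards reliability, BEST rewards occasional deep minima — so the package
keeps them as separate matrices and fits separate selectors for each.
`rank_transform()` then ranks the algorithms within each instance row
(rank 1 = lowest energy). Ties take average ranks: this is the standard
rank-statistics convention, and it is the only choice that preserves the
row-sum invariant n(n+1)/2 that several downstream checks rely on.

## The selector

`factorize()` computes a truncated SVD of the uncentered rank matrix,
R ≈ U~k~ Σ~k~ V~k~ᵀ, with k = 5 by default. Two conventions are worth
stating because they are easy to get silently wrong:

* **Scale placement.** The singular values are folded into the instance
  factors (U·Σ), leaving the algorithm factors orthonormal. The regression
  targets then carry the magnitude information and a predicted rank row is
  a plain inner product. Regressing onto U alone or U·Σ^½ would be
  equally legitimate; the choice is fixed here and recorded in the model.
* **No centering.** Every rank row has the same mean (n+1)/2, so the
  first singular component absorbs the common offset harmlessly; centering
  would only complicate reconstruction.

`fit_selector()` learns the feature-to-latent-factor map with random
forests. The reference protocol specifies a 100-tree forest with
scikit-learn's default behaviour; for a regression forest those defaults
mean *all* features are candidates at every split and trees are grown
essentially to purity. The `ranger` forests used here are therefore
configured with `mtry = p` and `min.node.size = 2` rather than ranger's
own `sqrt(p)`/5 defaults — with hundreds of mostly uninformative
descriptors, `sqrt(p)` splits dilute the signal enough to blur cluster
boundaries. Because no multi-response random forest is available, the
k-dimensional target is fitted as k single-output forests sharing one
configuration and deriving their seeds from the one master seed; this is
the per-dimension variant of the single multi-output ensemble and
predicts identically in the limit of rich trees. All selector randomness
flows from `selector_config(seed = )`, and fitted models serialize and
reload with bit-identical predictions.

`predict_ranks()` returns one score per algorithm (lower = better);
`select_algorithm()` takes the argmin, breaking exact ties first by the
lower training mean rank and then by portfolio order — a deterministic
rule that favours the safer algorithm when the model is indifferent.

## Evaluation protocol

`kfold_split()` makes seeded, balanced tenfold partitions.
`evaluate_selector()` refits the selector per fold — min-max normalization
is fitted on the training rows only and applied unclipped to the held-out
rows, so no test information leaks into the scaling — and records, per
held-out instance, the *true* aggregated energy of the chosen algorithm.
Methods are compared on a **joint ranking**: each instance's n standalone
energies plus one achieved-energy entry per meta-method (the selector, the
single-best solver, the virtual-best solver), ranked together with average
ties so a selector always ties the algorithm it picked. This puts selectors
and standalone algorithms on one scale, at the cost of the scale length
growing with the number of methods evaluated together.

The **single best solver** (SBS) is re-determined on each fold's training
rows (a whole-data mode exists for replication); the **virtual best
solver** (VBS) is the per-instance oracle argmin and lower-bounds every
method's achieved energy. The **random** baseline is the uniform pick
averaged over 1000 seeded draws; each draw is ranked by inserting the drawn
algorithm's energy into the fixed joint set, so the random row's noise does
not perturb the other methods' reported ranks. Its standalone-scale
expectation is (n+1)/2, which the tests verify by Monte Carlo.

`compare_feature_sets()` repeats the evaluation across named feature
tables under shared folds, reproducing the feature-set league table
(descriptors vs fingerprints vs top-importance subsets and their
concatenations).

## Feature engineering

The descriptor chain is `drop_zero_features()` →
`drop_near_constant()` → min-max normalization, in that order. "Almost
constant" is operationalised as a single value occupying ≥ 99% of
instances; the threshold is configurable because the underlying notion is
qualitative. Constant columns that survive to normalization map to 0
rather than erroring, keeping pipelines composable. Fingerprint tables are
881-bit binary PubChem Substructure Fingerprint vectors, accepted either
as CSV or as 881-character 0/1 strings per ligand, and validated to
exactly 881 binary columns.

`select_top_features()` implements both subset rules used downstream: an
importance cutoff (0.15 on normalized Gini importance is the reference
value) and a top-n rule with name-order tie-breaking.

## Landscape analyses

`feature_importance()` sums the raw impurity decreases across the k
per-dimension forests and normalizes the sum to 1. Summing raw (rather
than averaging per-forest normalized) importances weights each latent
dimension by the target variance it actually carries, so a near-constant
latent dimension cannot inject uniform noise into the report.

`cluster_algorithms()` applies average-linkage agglomerative clustering
with Euclidean distances to the algorithm latent factors (AVG-mode factors
by convention); linkage rule and metric are configurable since nothing in
the method forces them. `reduce_portfolio()` cuts that tree
deterministically: `lowest_pairs` accepts only leaf–leaf merges (pairs of
near-equivalent configurations), `one_higher` additionally accepts merges
of those pairs (clusters of up to four), and each cluster keeps its member
with the best training mean rank.

`embed_instances()` provides deterministic 2-D PCA and a seeded exact
t-SNE. The t-SNE is implemented inside the package (O(m²) affinities,
perplexity calibrated by bisection and capped at (m−1)/3, early
exaggeration 4 for 100 iterations, momentum 0.5→0.8, 400 iterations); the
perplexity actually used is recorded on the result.
`cluster_instances()` scans k-means over k ∈ [2, 15] and picks the k
maximising the mean silhouette coefficient; `cluster_profiles()` returns
the five-number summaries behind per-cluster feature boxplots.

## The synthetic benchmark

Real docking tensors require days of AutoDock compute, so the package
ships a generator with planted ground truth. `generate_benchmark()` draws,
for each of 4 instance clusters (instances assigned round-robin), a mean
energy per algorithm around a −7 kcal/mol baseline with Uniform(0, 1)
jitter, then lowers the cluster's designated winner `cluster_gap`
(default 2) kcal/mol below its best competitor; run energies are Gaussian
around those means. Winners differ across clusters by construction, so the
portfolio is genuinely complementary and a per-instance selector has
something to gain over the single best solver. Gaussian run noise is the
simplest model that makes AVG and BEST disagree (BEST is an extreme-value
statistic), mirroring how the best standalone algorithm can differ between
the two modes. With `cluster_gap = 0` the winner labels are generated but
left unconnected to the energies — a null benchmark on which winner
recovery should stay at chance.

Nine informative descriptor features encode cluster membership redundantly
(noisy 0.1/0.9 indicators, clipped to [0, 1]); 110 uniform-noise features
pad the table to 119 columns, the size of a cleaned real descriptor table,
so the importance-cutoff pathway has realistic sparsity to work against.
Fingerprints flip a cluster-specific 881-bit template with probability
0.05 per bit. What the generator does **not** emulate: realistic
descriptor marginals and correlations, heavy-tailed docking-energy errors,
and instance clusters of unequal size or overlapping winners. Passing the
recovery tests therefore demonstrates that the machinery is correct and
sensitive to planted structure, not that comparable accuracy would be
reached on real docking data.

## Problem sizes and defaults

The default benchmark is 300 instances × 12 algorithms × 50 runs — large
enough that the rank matrix, the latent factors and the CV machinery are
exercised at realistic aspect ratios, small enough that the full tenfold
evaluation runs in well under a minute on one core. The bundled analysis
scripts use run noise 0.1 kcal/mol against a 2 kcal/mol winner margin
(after averaging 50 runs the cell noise is ≈ 0.014 kcal/mol, so the AVG
argmin is effectively the planted winner and errors are attributable to
the selector, not the aggregation). A 1428 × 28 × 50 configuration —
the scale of the real study — is a one-line change to
`synthetic_config()` and remains feasible offline.

## Known limitations

* The joint-ranking interpretation of the league table (selector ranked
  among n+1 entries with ties to its pick) is one of two defensible
  readings of the protocol; the alternative — reporting the chosen
  algorithm's rank among the n standalones — can be computed from the
  `achieved` matrix in any `evaluation_report`.
* The per-dimension forest decomposition ignores correlations between
  latent targets; a true multi-output forest could share split structure.
* The exact t-SNE is quadratic in instances; beyond ~5000 instances a
  Barnes–Hut implementation would be needed.
* `reduce_portfolio()`'s cut rules are tree-topology heuristics; they
  reproduce the idea of "keep one of each similar group", not a unique
  mathematical optimum.
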