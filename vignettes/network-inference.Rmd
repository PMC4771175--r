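---
title: "Methods: proteomic network inference, benchmarking and consensus"
author: "ppinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic network inference, benchmarking and consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`ppinet` treats protein–protein interaction discovery from RPPA expression
matrices as a benchmarking problem: many estimators of "direct
association" exist, they disagree, and a curated edge set lets us measure
which ones work, aggregate the good ones, and interpret the resulting
consensus network. The pipeline assumes:

* expression values are continuous, complete after the configured
  missing-value policy, and comparable across samples within a cohort
  (inputs are expected to arrive normalized);
* interactions are undirected; correlation-family and
  partial-correlation-family weights are signed, mutual-information
  weights are unsigned and nonnegative;
* the benchmark edge set is informative but incomplete, which is why
  evaluation emphasizes precision at low recall rather than full-curve
  area.

## The synthetic study

The generator samples from a Gaussian graphical model (GGM). This is a
deliberate choice rather than a neutral one: the partial-correlation
family estimates exactly the GGM conditional-independence structure, so
parameter recovery on GGM draws is a meaningful correctness surface — an
estimator that cannot recover the generating support at n = 2000, p = 20
is wrong, not unlucky. The pieces:

* **Support**: Erdős–Rényi with the requested density. The default density
  of 9.29% matches the curated benchmark regime in which 162 antibodies
  form 13,041 candidate pairs and about 1,212 of them are curated edges.
* **Precision matrix**: random off-diagonal magnitudes (uniform on
  [0.4, 1]) on the support, ~30% of edges negative (so negative-dominant
  edge groups exist downstream), made positive definite by diagonal
  dominance (diagonal = absolute off-diagonal row sum + 1). Diagonal
  dominance is crude but reproducible and never fails; the retry/jitter
  path exists only as a numerical guard.
* **Cohorts**: i.i.d. multivariate normal draws from the inverse
  precision, plus independent N(0, noise_sd²) measurement noise. With
  `heterogeneity > 0` each cohort rescales a random subset of edge
  magnitudes (factors 0.25–1.75) before inverting, so cohorts share
  support but differ in strength — the analogue of tumor-type
  heterogeneity. The reference design (`pancan11_cohort_sizes()`) records
  the 11 cohort sizes from 127 to 747 samples.
* **Annotation**: a configurable fraction of antibodies is
  phosphospecific (default 51/187) or maps to two paralog genes, and at
  least one phospho/total antibody pair targets the same gene so the
  gene-level self-interaction skip in the mapping stage is always
  exercised.
* **Gene lists**: a rooted forest in which every child list is a subset of
  its parents, with species-tagged identifiers.

What the generator does **not** emulate: non-Gaussian marginals, batch
effects, antibody cross-reactivity, dependent noise, and the ascertainment
bias of curated edge sets (in real benchmarks the "gold" standard is
biased toward well-studied proteins). Passing tests on synthetic data
therefore demonstrate algorithmic correctness and calibration of the
machinery, not biological performance on tumor data.

Chain (cascade) fixtures are used throughout the tests because they are
the smallest structure exhibiting the transitive-correlation phenomenon:
in A–B–C, the marginal correlation of A and C is the product of the two
link correlations, while the partial correlation of A and C given B is
exactly zero.

## The thirteen estimators

* **pearsoncor / spearmancor** — sample (rank) correlation; no transitive
  cleanup at all; they serve as the baseline the other families must beat.
* **simpleparcor** — partial correlation from the inverse sample
  covariance, `w_ij = −Ω_ij/√(Ω_ii Ω_jj)`, with a Moore–Penrose
  pseudo-inverse fallback when the covariance is singular (n < p). This is
  the method most sensitive to the n/p ratio.
* **genenet** — the same formula on the Schäfer–Strimmer analytically
  shrunk correlation matrix (via `corpcor`); shrinkage intensity is
  estimated, not tuned.
* **glasso** — ℓ1-penalized precision estimation, implemented as the
  classic block coordinate descent over columns with an inner lasso
  coordinate descent. Correctness is checked in the tests through the KKT
  conditions (|W − S| ≤ ρ off-diagonal, with equality and matching sign on
  the support) rather than against a reference fit.
* **ridgenet / lassonet / elasticnet** — node-wise penalized regression on
  standardized columns (via `glmnet`, no intercept, no internal
  standardization), symmetrized by
  `sign(B_ij)·√(max(0, B_ij B_ji))`; conflicting signs yield weight 0. An
  explicit `penalty` in `params` fixes the penalty; otherwise it is chosen
  per node by 5-fold cross-validated prediction error over the grid. Fold
  assignment is a deterministic function of the seed. On standardized data
  the symmetrization is exact for ordinary least squares, which is why the
  ridge estimate at vanishing penalty must (and does) agree with the
  inverse-covariance route to 1e-2.
* **plsnet** — node-wise partial least squares (SIMPLS), component count
  cross-validated over 1–8 by default, same symmetrization.
* **aracne.a / aracne.m** — Kraskov k-nearest-neighbour mutual information
  (k = 3 by default; compiled kernel) followed by data-processing-
  inequality pruning: edge (i, j) is removed when its MI falls below the
  weaker side of any triangle, minus an additive tolerance `eps` or scaled
  by `1 − tau`. All removals are evaluated against the original matrix.
  Under this standard convention a *larger* tolerance prunes *less*; the
  monotonicity property tests assert that direction (shrinking the
  tolerance can only remove edges).
* **clr** — each MI value standardized against its row background (z
  clamped at 0), combined in quadrature; a flat MI landscape maps to the
  zero network.
* **mrnet** — maximum-relevance/minimum-redundancy greedy forward
  selection per target; a variable's directed score is its criterion value
  at selection; undirected scores are symmetrized by the maximum (the
  common convention; the alternative — averaging — changes little and is
  not exposed).

## Evaluation choices

* **Edge ranking**: |weight| descending; ties get average ranks (used by
  the consensus stage) and a deterministic lexicographic pair order for
  curve traversal and serialization, so reruns are byte-identical.
* **PR curves**: rankings are restricted to pairs inside the
  gold-standard universe before traversal; point t has precision TP(t)/t,
  recall TP(t)/|gold|.
* **Limited-recall AUPR**: trapezoidal integral of the piecewise-linear
  curve on [0, recall_max], default recall_max = 0.1, linearly
  interpolated at the window edge (at an exact tie the first point
  attaining the edge recall is used, i.e. the precision *before* the
  step-down). The integration rule shifts absolute areas slightly relative
  to a step-function rule but not method order; the bound AUPR ≤
  recall_max holds by construction.
* **Grid search**: exhaustive, deterministic first-in-grid tie-break.
  Default grids: glasso ρ — 8 log-spaced points in [0.01, 1];
  ridge/lasso/elastic-net penalties — 10 log-spaced points in [1e-4, 1e2],
  elastic-net crossed with mixing {0.25, 0.5, 0.75}; PLS components 1–8;
  ARACNE eps/tau {0, 0.05, 0.1, 0.15, 0.2}. The grids span the under- to
  over-regularization regimes; methods whose selection is internal
  (cross-validated regression penalties) or parameterless evaluate a
  single cell.
* **Method ranking**: overall AUPR (sum over cohorts; higher better) and
  overall AUPR rank (sum of per-cohort average ranks; lower better); the
  high-performer set is the intersection of the top-k lists under both
  criteria (k = 6 by default).

## Consensus choices

Three decisions here were genuinely open:

1. **Combining signed and unsigned weights.** Mutual information lives in
   nats, correlations in [−1, 1]; naive averaging lets whichever scale is
   larger dominate. Each method's |weight| vector is min–max scaled to
   [0, 1] per cohort before averaging, and the consensus sign is the
   majority sign among the signed methods (ties and all-unsigned sets
   default to positive). Signs are thus tracked separately from
   magnitudes.
2. **Threshold selection.** For each candidate rank threshold the
   union-edge × cohort weight matrix is built and the variance fraction
   explained by the first three principal components of the cohort
   vectors is recorded; the threshold sits at the inflection of this
   series, found as the maximum-magnitude discrete second difference
   after window-3 smoothing. With three or fewer cohorts the first three
   components always explain everything, the series is constant, and the
   selector falls back to the median candidate with a warning — threshold
   selection needs at least four cohorts to be informative, which is why
   the packaged example study has four.
3. **Weights of non-significant pairs.** Discovery-set members keep their
   consensus weight in every cohort (not zero where they miss the
   threshold); recurrence — the count of cohorts where the pair beats the
   threshold — carries the significance pattern instead. Clustering on
   full weights and annotating with recurrence separates "how strong" from
   "how often".

## Modules and mapping

Edge groups are Ward-linkage (ward.D2) / Euclidean hierarchical clusters
of the edges × cohorts weight vectors, cut at three and labelled by mean
pan-cohort weight (highest → positive dominant, lowest → negative
dominant, remainder heterogeneous). Recurrence is annotation only, not a
clustering feature.

Community detection runs five igraph algorithms on the unweighted
discovery graph (a weighted mode exists but is off by default, since edge
weights and topological modularity answer different questions). The
spin-glass model requires connectivity and is run per connected component
with offset module ids; stochastic algorithms draw from seeded streams. A
failing algorithm is dropped with a warning and the consensus denominator
adjusted. The co-assignment frequency matrix (entries in multiples of
1/5) is cut into consensus modules by the same Ward/Euclidean procedure,
modules relabelled by decreasing size. Per-module statistics report edge
counts split by group, antibody counts split by phosphospecificity,
average degree 2E/N over intra-module edges only, and the top-3 hubs.

Gene-list mapping follows the average-interaction-strength definition:
per cohort, each significant pair is reduced to its two gene sets;
intersecting sets are gene-level self-interactions and are skipped; a
list matches when both sets hit it; the contribution is
|consensus weight| / list size; cells are means over matched interactions
and stay missing (never zero) when nothing matched, so sparse matches are
not diluted. Absolute weights are the default (a signed variant is
available by argument). Hierarchies are DAGs: multi-parent lists trace to
several roots, cycles are rejected by name, depth is the shortest
distance from a root.

## Determinism and problem sizes

Every stochastic operation derives its stream from an explicit seed
(`with_seed` restores the caller's RNG state; per-stage seeds are derived
from the configuration seed and a stage label). Writers emit fixed column
orders, LF endings and 10 significant digits, so a pipeline run is a pure
function of its configuration: the test suite asserts byte-identical
reruns.

The shipped experiments use sizes at which the statistical claims are
already unambiguous while keeping runs fast: support recovery on 20
antibodies at density 0.1 with n = 2000 (noise-free, where all
partial-correlation variants reach the AUPR ceiling and full true-edge
overlap); cascade pruning on a 10-node chain at n = 2000; the end-to-end
configuration on 12 antibodies across 4 cohorts of 45–80 samples.
Law-of-large-numbers checks use n = 10,000–15,000 on 5–6 variables.

## Known limitations

* The lasso variant is plain cross-validated lasso; the adaptive-lasso
  refinement used by some implementations is omitted, which may change
  rankings slightly in heavy-tailed regimes.
* The k-NN MI estimator assumes continuous, tie-free data; heavily
  discretized input will bias it (ties make strict-inequality neighbour
  counts undercount).
* Threshold selection is heuristic (smoothed second difference); on flat
  series it degrades to the median candidate by design rather than
  failing.
* The pseudo-inverse fallback of `simpleparcor` is known to be a weak
  estimator when n < p; it is kept because measuring that weakness is part
  of the point.
* The GGM generator cannot certify performance on real RPPA data; it
  certifies the machinery.
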