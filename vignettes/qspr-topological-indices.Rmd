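---
title: "Topological-index QSPR models for combustion enthalpy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological-index QSPR models for combustion enthalpy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsprgraph)
```

## The modeling problem

The standard combustion enthalpy of an organic compound — the heat
released on complete oxidation of one mole at standard conditions — is
expensive to measure and is classically estimated by group-contribution
schemes that require manual functional-group assignment.  A
quantitative structure–property relationship (QSPR) sidesteps that:
the molecule is reduced to a labeled graph, the graph to a handful of
numeric descriptors, and the descriptors to a prediction through a
regression model.  `qsprgraph` implements that pipeline end to end for
the positive magnitude of the combustion enthalpy, written
$-\Delta_c H^\circ$ and carried in kJ·mol$^{-1}$ throughout.  Working
with the positive magnitude keeps the logarithm in RMSLE defined and
makes all targets directly comparable across compound families.

## Molecular graphs

A SMILES string is parsed into the graph $G = (V, E)$: one node per
atom, one edge per bond, no loops, no multi-edges.  Two conventions
matter and are fixed package-wide:

* **Explicit hydrogens.** Indices are computed on the graph after every
  implicit hydrogen has been added as a degree-1 node.  This is the
  convention under which benzene's Estrada index is 28.7159 and its
  Gutman index 570; the hydrogen-suppressed ring would give about 14.4
  and 108 instead, so the convention is identifiable from worked values
  and is not negotiable after the fact.
* **Unweighted edges.** A double or triple bond contributes exactly one
  edge.  Bond orders and aromaticity are recorded during parsing only to
  count hydrogens: a neutral non-aromatic atom receives
  (default valence − sum of incident bond orders) hydrogens, with
  default valences B 3, C 4, N 3, O 2, P 3, S 2, halogens 1.  Aromatic
  ring atoms are treated as sp² — one valence unit belongs to the
  delocalized system, so an unsubstituted aromatic carbon with two ring
  neighbours gains one hydrogen.  Bracket atoms receive exactly their
  stated hydrogen count, never more.

Node numbering is deterministic: heavy atoms in SMILES token order,
then hydrogens appended in owner-atom order.  Adjacency matrices are
therefore reproducible bit for bit, which the test suite exploits.
Multi-fragment SMILES (containing `.`) are rejected rather than
truncated to the largest component — silently dropping a fragment would
corrupt every distance-based index.  Stereochemistry, isotopes and
tautomer handling are out of scope.

## Descriptors

For a graph with adjacency matrix $A$, eigenvalues
$\lambda_1 \ge \dots \ge \lambda_n$ and shortest-path distances
$d(i,j)$:

* **Estrada index** $EE = \sum_i e^{\lambda_i}$, a spectral measure of
  subgraph centrality, computed by full symmetric eigendecomposition
  (exact for the molecule sizes involved; no truncated series).
* **Wiener index** $W = \sum_{i<j} d(i,j)$, an exact integer.
* **Gutman index** $\sum_{i<j} d(i,j)\deg(i)\deg(j)$, an exact integer.
* **Node centralities**: degree; betweenness as a raw geodesic count
  over unordered source–target pairs with endpoints excluded (no
  normalization, so leaves score 0); closeness as the plain reciprocal
  $1/\sum_{t\ne v} d(v,t)$ — deliberately *not* the $(n-1)$-scaled
  variant most graph libraries default to; and eigenvector centrality
  as the principal eigenvector of $A$, oriented nonnegative and scaled
  to unit Euclidean norm.

Eigenvector centrality deserves a numerical note.  Power iteration is
the textbook route, but molecular graphs are mostly bipartite (any
acyclic or even-ring structure), where the adjacency spectrum is
symmetric and plain iteration oscillates; the standard $A + I$ shift
fixes that but leaves a spectral gap that shrinks roughly as $1/n^2$
along chain-like molecules, so a $10^{-10}$ tolerance needs tens of
thousands of iterations on a C$_{30}$ alkane.  The package therefore
extracts the principal eigenvector from the same full symmetric
eigendecomposition used for the Estrada index: deterministic, exact to
machine precision, and independent of gap size.  The degenerate case of
an exactly tied principal eigenvalue raises an error rather than
returning an arbitrary basis vector.

Node-level centralities are pooled to one value per molecule before
modeling.  The aggregation rule is not dictated by the underlying
science, so it is a parameter: arithmetic mean by default (stable under
homologous-series growth), with `sum` and `max` available; the choice
is recorded in the output's `aggregation` attribute.  The full
descriptor vector is, in fixed order: Estrada, Wiener, Gutman, then
aggregated degree, betweenness, closeness, eigenvector.

## Regression models

* **Fixed multilinear predictor.** `eq13_predict()` applies the
  published three-index linear combination
  $-\Delta_c H^\circ = 90\,EE - 1.0789\,W + 0.2822\,Gut - 417.6882$
  with frozen coefficients — a reference model, never refit.
* **OLS / ridge.** Ridge solves the penalized normal equations with the
  intercept unpenalized and predictors on their given scale; z-score
  first if comparable shrinkage across features is wanted.  At
  $\alpha = 0$ ridge reproduces OLS to machine precision (tested).
* **Huber.** Iteratively reweighted least squares for the loss that is
  quadratic below the switch point $\epsilon$ and linear beyond, plus
  an L2 term $\alpha$.  The residual scale is re-estimated each
  iteration as MAD$/0.6745$, so $\epsilon$ operates on a
  studentized-residual scale, the common robust-regression convention.
  Convergence: relative coefficient change below $10^{-6}$, at most
  1000 iterations, error on failure.
* **CART / random forest / extra trees.** Splits minimize the weighted
  child mean squared error; candidate thresholds sit at midpoints of
  consecutive sorted unique feature values, and mathematically tied
  scores are resolved to the lowest feature index, then the lowest
  threshold (ties are detected with a tolerance proportional to the
  node's total sum of squares, because two equal scores computed along
  different prefix-sum paths differ by floating-point noise).  Leaves
  predict their training mean, so every ensemble prediction is bounded
  by the training target range.  The forest averages `n_estimators`
  trees (default 100) grown on bootstrap resamples; `mtry` defaults to
  all features, matching the defaults of the reference configuration
  for regression.  The extra-trees variant draws one uniform random
  threshold per candidate feature inside the node's range and keeps the
  best; it bootstraps by default here — the reference setting — even
  though the canonical algorithm uses the full sample
  (`bootstrap = FALSE` restores that).  Identical seeds give
  bit-identical models.

Impurity importance accumulates each split's SSE decrease per feature,
averages over trees and normalizes to sum 1.  Because impurity
importances are biased toward high-cardinality features, the package
also provides model-agnostic Monte-Carlo Shapley attribution
(`mc_shapley()`): for each sampled feature ordering, instance features
replace a randomly drawn background row one at a time and the marginal
output changes are averaged.  The estimator is unbiased, reports a
per-feature Monte-Carlo standard error, satisfies the null-player axiom
exactly, and its additivity defect is bounded by the summed Monte-Carlo
error (tested).  Defaults: 200 permutations, background capped at 200
seeded rows.  Exact TreeSHAP is intentionally not reimplemented; the
Monte-Carlo estimator is model-agnostic and its error is quantified.

## Evaluation protocols

Metrics are MAE, RMSE, MAPE, RMSLE and $R^2$.  MAPE is reported as a
fraction (0.075 means 7.5%), matching how such values are usually
quoted for this property; a `percent` flag rescales.  The protocols —
70/30 hold-out (`round(0.7 n)` training rows), 10-fold CV, random
hyperparameter search with 5-fold inner CV, nested 5×3 CV, learning
curves — all refit the z-score scaler *inside* every training fold.
The scaler uses population standard deviations and maps constant
columns to zero with a warning.  Fold standard deviations are sample
(ddof 1) values.  Degenerate fold evaluations (a single validation
sample, or a linear model emitting a slightly negative prediction that
leaves RMSLE's domain) yield `NA` for the undefined metric rather than
aborting the protocol.  The hold-out split is a plain uniform
permutation: the target is continuous, so there is nothing to stratify.

## Clustering the topological space

`kmeans_fit()` is k-means++ seeding followed by Lloyd iterations to an
assignment fixpoint (cap 300), one initialization by default; empty
clusters are reseeded at the point farthest from its assigned centroid.
Inputs should normally be z-scored: the Gutman index is two orders of
magnitude larger than the Estrada index on typical molecules and would
otherwise dominate every Euclidean distance.  Raw-space clustering
remains possible by simply not scaling.  DBSCAN (defaults
$\varepsilon = 0.1$, 20 samples, Euclidean) provides the density-based
comparison, labeling noise $-1$.  Validity uses the standard silhouette
(singleton clusters score 0; $b$ is the mean distance to the nearest
*other cluster's members*, not to its centroid) and the centroid-based
Davies–Bouldin score.  On the two-cluster fixture $\{0,1\}$ vs
$\{10,11\}$ these give $0.8997$ and $0.1$; the silhouette value is the
exact mean of $(9.5/10.5, 8.5/9.5, 8.5/9.5, 9.5/10.5)$ — a commonly
mis-simplified example, since using the outer points' $b = 10.5$ for
all four points would give $0.9048$.

## The synthetic-data generator

`series_smiles()` builds homologous families constructively: n-alkanes,
1-alkenes, 1-alkynes, n-alkylbenzenes, n-alkylcyclopentanes and
-cyclohexanes, primary amines, mono- and di-carboxylic acids
(HOOC–(CH₂)$_k$–COOH), and 1-halo-alkanes, with systematic names up to
C40 chains.  `simulate_enthalpy()` then draws targets
$\beta_0 + \beta_1 EE + N(0, \sigma^2)$, truncated-resampled to stay
positive.  Defaults $\beta_1 = 90$ kJ·mol$^{-1}$ per Estrada unit
(anchored to the fixed multilinear model's Estrada coefficient) and
$\sigma = 50$ kJ·mol$^{-1}$, roughly the residual scale a three-index
linear model leaves on real combustion data.  What this emulates is
the near-linear Estrada–enthalpy trend within and across homologous
series; what it does **not** emulate is heteroatom-family offsets,
experimental error structure, state-of-matter effects, or any
nonlinearity the real property shows across diverse chemistries.
Passing tests on synthetic data therefore demonstrate that the
machinery (parsing, indices, fitting, selection, attribution) is
correct and reproducible — not that a three-descriptor model attains
any particular accuracy on real measurements.

## Problem sizes and budgets

The test suite runs at desk scale by choice: random-graph oracles at
$n \le 12$ (50 seeded instances per oracle), alkane series to C30,
forests of 10–100 trees on 30–120 samples, 7 blobs × 30 points for
cluster recovery, and 100–400 Shapley permutations.  These sizes are
where the independent oracles (Floyd–Warshall, exhaustive split
enumeration, matrix-exponential trace, closed-form linear Shapley) are
cheap and exact, which is what makes the comparisons meaningful.

## Known limitations

* The SMILES dialect is the organic subset plus bracket atoms; no
  stereochemistry, isotopes, or multi-fragment inputs.
* Aromatic perception is minimal (lowercase ring atoms treated as sp²);
  exotic aromatic systems that require Kekulization for hydrogen counts
  are outside the supported subset.
* Indices are computed densely; graphs beyond a few thousand atoms
  would need sparse methods the package does not provide.
* The fixed-coefficient multilinear model is reproduced as published;
  whether it was fit on a full dataset or a training split is not
  stated in its source, so it is treated purely as a frozen predictor.
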