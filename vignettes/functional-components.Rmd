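---
title: "Discovering reproducible functional components with fcmodules"
author: "fcmodules authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering reproducible functional components with fcmodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmodules)
```

# The model

`fcmodules` treats a bulk or single-cell expression profile as a linear
combination of a fixed set of latent transcriptomic modules.  For gene
$i$ in a sample,

$$ g_i = \sum_{f=1}^{n} w_f \, F_{fi} + \epsilon_i, $$

where the $F_f$ are *functional components* (FCs) — continuous
gene-loading vectors — the $w_f$ are per-sample coefficients, and
$\epsilon_i$ is unmodeled noise.  Unlike binary gene sets, FC membership
is smooth, which better reflects gene co-dependency; unlike principal
components, FCs are estimated by independent component analysis (ICA),
whose non-Gaussianity objective matches the super-Gaussian (sparse,
heavy-tailed) character of expression data.  Gaussian directions carry
no ICA signal, which is why the package reports a per-component
negentropy and flags unidentifiable (near-Gaussian) solutions instead of
pretending to recover them.

The discovery pipeline is: preprocess a large expression collection,
reduce it to a *representative compendium* of cluster medoids, whiten by
SVD, choose the component count by parallel analysis, run ICA many
times, and align the runs to quantify reproducibility.  Application
tooling then projects new studies into FC space and supports
differential testing, annotation, fingerprinting, and classification.

# Preprocessing

`preprocessExpression()` applies, in this fixed order:

1. **quantile normalization between arrays** — every column is mapped
   onto the mean order statistics (ties receive the average of the tied
   reference values);
2. **gene centering** — every row mean becomes 0;
3. **per-array scaling and centering** — every column ends with mean 0
   and sample SD 1 (the $n-1$ denominator everywhere).

The order matters: the column operations are applied last, so column
means are exactly zero afterwards, which the whitening step relies on.
Zero-variance arrays are an error rather than silently dropped.  New
query studies are normalized freshly and independently per study by
default; the functions operate on whatever matrix they are given, so a
caller who wants to normalize a query against a stored reference
distribution can do so explicitly.

# Representative compendium

Over-represented phenotypes would otherwise dominate the ICA objective,
so the collection is reduced before whitening.  Distances between
arrays are $1 - \rho$ (Spearman by default), clustered with average
linkage.  The cut height can be supplied directly or detected from a
k-nearest-neighbor distance curve: the curve of every sample's distance
to its $k$-th neighbor is sorted and the knee is the point of maximum
perpendicular distance from the chord joining the curve's endpoints.
This rule was chosen for determinism — a visual knee read is not
reproducible — and a near-linear curve (no knee) is an error with a
manual `height` override as the escape hatch.  Clusters with fewer than
`minSize = 5` members are discarded; each surviving cluster contributes
its medoid (member minimizing summed distance to the rest; ties go to
the smallest sample index).

# Whitening and the number of components

`svdWhiten()` decomposes the preprocessed compendium $X = U D V^T$ and
returns $Y = \sqrt{g-1}\,U$ restricted to the leading $n$ columns, with
covariance eigenvalues $e_i = d_{ii}^2/(g-1)$.  The $\sqrt{g-1}$ factor
makes $Y^T Y = (g-1) I$, keeping the eigenvalues commensurate with the
unbiased variance estimate.

`parallelAnalysis()` chooses $n$: it simulates i.i.d. $N(0,1)$ matrices
of the same shape, collects the per-index quantile of the simulated
eigenvalues as a bias (median for Horn's method, 0.95 quantile for
Glorfeld's), and retains components whose bias-corrected eigenvalue
$e_i - \mathrm{bias}_i$ exceeds 1.  Two deliberate choices are recorded
here.  First, the simulated matrices are plain $N(0,1)$ without
standardization; their eigenvalues are scaled by the same $(g-1)$
divisor so bias and observation live on one scale.  Second, the
retention rule is the "corrected eigenvalue > 1" form rather than the
more common $e_i > \mathrm{bias}_i$; the conventional rule is available
via `rule = "conventional"` and, being strictly more permissive, never
retains fewer components.  Simulation eigenvalues are computed from the
small-side crossproduct, which is algebraically identical to an SVD of
the simulated matrix.

# Multi-run ICA

`runICA()` fits $Y = S A$ with $S$ ($g \times n$) the sources and $A$
($n \times n$) the mixing matrix, by symmetric fixed-point iteration
over an orthogonal unmixing matrix.  Convergence is declared when the
maximum change in unmixing directions falls below `tol = 1e-6`, with
`maxIter = 8000`; a non-convergent run is returned flagged, never
silently.  Each source column is standardized (mean 0, SD 1), with the
compensating scale folded into $A$ so $Y = SA$ holds exactly.

Two backends share this machinery:

* **logcosh** (default): the classical $\log\cosh$ negentropy
  approximation.  Fast, deterministic given a seed, and sufficient for
  the super-Gaussian sources the model targets.
* **proden**: re-estimates each source's log-density every iteration as
  a tilted Gaussian on a grid of `gridPoints = 2000` points (a Poisson
  smooth of binned counts with a log-normal-density offset) and uses
  the estimated score function in the update.  This follows the
  nonparametric-contrast family of ICA algorithms, which are more
  sensitive to unusual source shapes at a real computational cost.

Negentropy totals are comparable only within a backend (each backend
scores with its own contrast), so `selectBest()` refuses mixed-backend
lists.  The backends also accept an `order` option (default 11) that is
recorded in the solution's parameter list for provenance but not
interpreted.  Random initialization draws a seeded orthogonal matrix; a
batch of `runs` repeats uses seeds `baseSeed + 1 .. baseSeed + runs`.

`canonicalize()` makes solutions comparable across runs: each component
is sign-flipped to nonnegative sample skewness (the skewness-based sign
convention common in large-scale ICA work), then components are ordered
by decreasing skewness with ties broken by original index.

# Aligning runs and measuring stability

Components from run $k$ are matched to the best solution through the
sign-invariant cost

$$ r^- = \tfrac{1}{2}(1-\rho), \quad r^+ = \tfrac{1}{2}(1+\rho), \quad
   C = \min(r^+, r^-), $$

minimized over perfect matchings by an exact $O(n^3)$ Hungarian solver
(`solveAssignment()`; an approximate or greedy matching would
systematically overstate instability).  The signed permutation $P$
carries $+1$ where $r^- < r^+$ and $-1$ where $r^- \ge r^+$ — the tie
$\rho = 0$ deliberately lands on the $-1$ branch — so the aligned
correlations $c_i = \mathrm{cor}(S^0_i, (S^k P)_i)$ are always
nonnegative.  One indexing subtlety: with $B_{ij} = 1$ meaning
reference component $i$ matched run component $j$, the matrix that
right-multiplies $S^k$ must place its sign at position $(j, i)$, i.e.
$P$ has the transpose support of $B$.  `stabilitySummary()` reports the
per-FC mean, SEM and maximum of $c$ across runs (SEM taken per FC over
runs), and `subsampleStability()` repeats discovery on column
resamples — whitened with the *fixed* reference component count so
components remain comparable — to expose components that only exist in
the full collection.

# Annotation

For each FC, genes whose loading lies strictly more than $z = 3$ SD
above (below) that component's own mean form the up (down) module; the
union is the active-gene set.  Mean and SD are per-column, not pooled —
components differ in tail weight, and a pooled threshold would let
heavy-tailed components flood the modules.  Overlaps with gene
signatures are reported as a percentage of the signature size, tested
with the hypergeometric upper tail (`stats::phyper`), and adjusted by
Benjamini–Hochberg over all FC–signature pairs with significance at
adjusted $p < 0.01$.  `bhAdjust()` accepts an explicit family size $N$
larger than the number of supplied p-values, matching analyses where
the family is "all FCs" (e.g. 139) or "all genes" even when only a
subset is carried forward.  The enrichment universe defaults to the
genes in the loading matrix and is overridable.

# Projection and its two conventions

`projectToFC()` computes $Q_{FC} = S^T Q_{gene}$ over the intersection
of gene universes; genes missing from the query are dropped from $S$
rather than imputed as zero, and the realized coverage is reported with
a hard floor (default 90%) below which projection refuses to proceed.
Raw gene loadings are the default; `unitNorm = TRUE` rescales each
component to unit Euclidean norm first.  Both conventions are
first-class because the methodology this package implements has used
both in different analyses without stating a single rule; the package
does not resolve that discrepancy, it exposes the flag and defaults to
raw loadings.

Neighbor search retains reference samples correlating above
`minCor = 0.95` (strict) with a group member, then drops those
neighboring fewer than $\lceil \mathrm{minFrac} \cdot |group| \rceil$
members.  Tissue fingerprints store labelled FC-score vectors with
per-label medoids; queries are annotated by the label with the highest
median correlation.

# Evaluation harness

* **Differential FC testing** uses two-sided unpaired t-tests per FC.
  Welch's unequal-variance form is the default — group variances in
  projected scores are routinely unequal — with `equalVar = TRUE`
  restoring the pooled form.  BH adjustment takes an explicit family
  size.
* **Clustering quality**: purity and per-cluster Gini impurity against
  mega-class labels, with majority ties going to the lower-indexed
  class and flagged; cophenetic correlation compares trees.
* **Classification**: one-vs-one linear SVMs (`e1071`, cost 1 — the
  regularization constant is otherwise unspecified in the methodology
  and 1 is the library default) with majority voting; vote ties are
  indeterminable calls (IDC), the call rate is the fraction of
  determinable calls, and per-class sensitivity is computed among
  called specimens of that class (this is the reading consistent with
  published per-class confusion-table arithmetic).  Folds are
  stratified per class.
* **Subsampling experiment**: per run, a held-out test set is drawn;
  training pools are subsampled at each fraction with `repeats`
  samplings (fraction 1.0 runs once per run, without repeats); FC-space
  and gene-space SVMs are compared per sampling by McNemar's test with
  continuity correction, with perfect agreement reported as
  "identical" rather than a p-value.  Undefined metrics (e.g. PPV of an
  all-negative predictor) are excluded from averages and counted, never
  coerced to 0.  Seeds derive as `seed + run` per run and
  `runSeed * 1000 + repeat` per repeat — arbitrary but fixed, so the
  whole experiment is bit-reproducible.  `runs` defaults to 10; the
  methodology's own description of the run count is internally
  inconsistent (10 in one place, 100 in another), so the argument is
  explicit and the default follows the procedural description.

# The synthetic-data generator

`genMixture()` draws $n$ independent standardized sources over $g$
genes — Laplace by default (symmetric, excess kurtosis 3, provably
super-Gaussian), with exponential (asymmetric) and Gaussian-scale-
mixture families to stress skewness ordering and the density-estimating
backend, and a Gaussian family as the unidentifiable control — mixes
them with an orthogonal or unconstrained random matrix, and adds
optional i.i.d. noise.  `genTwoClassStudy()` plants a coefficient shift
of `effectSize` (in coefficient-SD units) on chosen FCs between two
groups, with optional per-batch gene intercepts (`batchSd = 3`, chosen
so the batch dominates gene-space variance the way strong multi-center
effects do, while balanced batches leave FC-space contrasts intact).
`amariError()` is the recovery oracle: the normalized Amari index is 0
exactly when the estimated unmixing is a scaled signed permutation of
the truth.

What the generator does *not* emulate: probe-level effects, intensity-
dependent noise, saturation, correlated gene blocks beyond the planted
components, or realistic tissue hierarchies.  Passing tests therefore
demonstrate correctness of the algorithms under the model's own
generative assumptions, not performance on any particular real
compendium.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberately modest
sizes chosen as representative of the algorithms' behavior: whitening
checks on matrices up to $500 \times 25$; source recovery at
$g = 2000$, $n = 5$, noise SD 0.05 over 10 seeds; signed-permutation
recovery exhaustively cross-checked against brute-force matching for
$n \le 6$; parallel analysis on $200 \times 30$ matrices with 100–200
simulations per call (the discovery default remains 5000); differential
calibration over 50 null studies.  Convergence tolerance is $10^{-6}$
on unmixing directions; whitening identities are asserted at $10^{-8}$
relative tolerance; exact combinatorial quantities (Hungarian matching,
hypergeometric tails, BH) are asserted to machine precision against
independent enumeration oracles.

Known limitations: negentropy scores are contrast-specific and not
comparable across backends; ICA cannot recover Gaussian components
(reported via near-zero negentropy rather than error); the knee rule
assumes a single dominant curvature change; and subsampling stability
deliberately reuses the reference component count, so it measures
reproducibility of *those* components, not re-selection of $n$.
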