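---
title: "Methods: chemical space mapping and visual validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical space mapping and visual validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemspacemap)
```

# The procedure and its assumptions

`chemspacemap` operationalises one idea: if a QSAR model is built on a set of
features, then the place to inspect its behaviour is a low-dimensional map of
exactly those features. The pipeline is a chain of standard steps —
featurisation, dissimilarity, clustering, 3D embedding — followed by
diagnostics that quantify how much the map can be trusted and annotations
that put validation results onto it.

The central assumption is the similarity principle: compounds close in
feature space tend to have similar activity. Every diagnostic here measures a
way this assumption (or its 3D projection) can fail:

* the map itself can be unfaithful (embedding quality, per-compound stress);
* the features can be blind to an activity difference (identical-feature
  conflicts, infinite SALI);
* the activity landscape can be genuinely rugged (finite SALI cliffs);
* the model can be asked to extrapolate (applicability domains).

# Distances and embeddings

Numeric descriptors are standardized to mean 0 and unit *population* variance
before Euclidean distances, so that no descriptor dominates by scale alone.
Binary fragment features use the Tanimoto distance; two all-zero fingerprints
are defined to be identical (distance 0) rather than undefined, since a
compound matching no fragment carries no distinguishing information either
way.

**PCA** projects onto the top three principal components. Sign of each
component is fixed so that its largest-magnitude loading is positive; this
makes coordinates reproducible across runs and BLAS implementations, which
matters because the package promises byte-identical re-runs from a stored
configuration. When the data have intrinsic dimension at most 3, the
projection is an isometry and the embedding quality is exactly 1 (this is a
tested property, to 1e-9).

**Sammon mapping** minimises
$E = \big(\sum_{i<j}\delta_{ij}\big)^{-1}\sum_{i<j}
(\delta_{ij}-d_{ij})^2/\delta_{ij}$,
which, unlike raw least squares on distances, weights small distances up and
therefore preserves local neighbourhoods. Numerical choices:

* initialisation from classical metric MDS (PCoA) of the input distances —
  deterministic, so the whole embedding is deterministic and the stored seed
  is provenance rather than a hidden degree of freedom;
* Sammon's diagonal-Newton update with step factor ("magic factor") 0.3,
  plus step halving whenever a proposed step would increase the stress; the
  objective is therefore monotone nonincreasing by construction, and the
  acceptance suite asserts it;
* convergence when the relative stress change drops below `tol = 1e-9`, with
  `max_iter = 500`; non-convergence returns the best configuration found with
  a warning and a `converged = FALSE` flag;
* pairs with $\delta_{ij} = 0$ are excluded from the sum. Compounds at zero
  distance are collapsed to one representative before optimisation and pinned
  to its coordinates afterwards; this is common in fragment spaces, where
  many compounds share a fingerprint.

**Clustering.** k-means (on coordinates) or hierarchical clustering with
average or Ward linkage (on distances). The automatic cluster count
maximises the mean silhouette width over $k \in \{2, \dots, \min(15, n-1)\}$
on the input distances. The original approach this emulates used a dynamic
tree cut; silhouette maximisation was chosen as the replacement because it
works identically for every clustering method and distance, needs no extra
dependency, and preserves the user-facing behaviour ("the number of clusters
is chosen automatically"). k-means ties are resolved by a fixed seed with 10
deterministic restarts.

# Embedding quality and stress

Global quality is the Pearson correlation between the $n(n-1)/2$ unordered
feature-space distance pairs and the corresponding 3D Euclidean distances;
using each pair once avoids double counting, and raw (not squared) distances
are used — the measure is a correlation of distances, not a stress. The 0.6
warning threshold marks the conventional boundary to moderate/weak
correlation. Per-compound stress is $1 - r_i$ over compound $i$'s distances
to everyone else; a compound whose distance vector is constant (a duplicate
in fragment space, typically) gets stress 0 with a degeneracy flag rather
than an error, because such compounds are common and not individually
informative.

# Subset specificity

Given a selected subset (a cluster, a neighbourhood, one compound), every
feature is scored for how specifically it characterises the subset:

* **nominal features**: χ² goodness-of-fit of the subset's category counts
  against expected counts from whole-dataset proportions. This deliberately
  compares subset against the *entire* dataset (not the complement): the
  question is "is this subset unusual for the dataset?".
* **numeric features, subset size ≥ 2**: one-way ANOVA between subset and
  complement. ANOVA requires disjoint groups, hence the complement here; the
  asymmetry with the χ² route is intentional and documented.
* **numeric feature of a single compound**: ANOVA is inapplicable, so the
  value is binned and the χ² test applied to the one-hot bin membership.
  Binning is equal-width starting at 20 bins, decreasing the bin count by one
  and re-binning until no bin is empty (strictly decreasing, so it
  terminates; two distinct values always support two bins). Interior bin
  edges are half-open with values on an edge falling right; the last bin is
  closed.

p-values are clamped into $(0, 1]$ and the ranking sorts ascending with a
stable sort. No multiple-testing adjustment is applied to the ranking — it is
an exploratory ordering, not an inference — but a Bonferroni column is
emitted for information. Expected counts below 1 are tolerated and flagged
rather than refused, again because the use is exploratory.

# Activity cliffs

$\mathrm{SALI}_{ij} = |A_i - A_j| / (1 - sim_{ij})$. For fragment features the
similarity is Tanimoto; for numeric features this package uses
$sim = 1 - d/d_{\max}$ over standardized Euclidean distances — a design
choice (the field has no single convention for numeric-feature SALI), kept
configurable by passing any similarity matrix. Pairs with $sim = 1$ and
different activity are flagged infinite and reported by count per compound;
they are excluded from the mean/SD/max aggregates so those stay finite while
the conflict phenomenon remains visible. The identical-feature conflict
detector is the exact combinatorial counterpart: it returns precisely the
pairs whose SALI is infinite under a similarity that equals 1 iff the
feature vectors are equal (a tested equivalence).

# Applicability domains

Three methods with a common contract (score, threshold, inside ⇔ score ≤
threshold; larger threshold factor never shrinks the inside set):

| method | score | threshold | default |
|---|---|---|---|
| centroid | Euclidean distance to the feature-mean compound | factor × mean score | factor 3 |
| leverage | $h_{ii}$ of $X(X^\top X)^{-1}X^\top$, $X = [1\,|\,\text{features}]$ | factor × (p+1)/n | factor 3 |
| k-NN | mean distance to k nearest neighbours | factor × mean score | k 3, factor 3 |

Centroid and k-NN scores are computed on standardized features; leverage is
affine-invariant so standardization is unnecessary. The leverage threshold
constant is the conventional $3\tilde p/n$; the underlying text states no
cutoff, so the factor is exposed. k-th-neighbour ties are broken by compound
index for determinism. The characteristic difference between the methods —
leverage excludes a compound extreme in one *correlated* feature that the
centroid distance misses; k-NN tolerates a tight far-away group that both
centroid methods would excise — is asserted on constructed data in the test
suite.

# Validation aggregation

Repeated validation produces several predictions per compound; the
aggregation rules are: mean for numeric predictions with per-compound RMSE
as error; positive-class ratio and misprediction ratio for binary endpoints
(with an `always_wrong` flag, the compounds misclassified in every
repetition); strict majority or `"inconclusive"` for multi-class; and the
inside-ratio for AD flags. $R^2$ is defined as $1 - SSE/SST$ (the scorer
convention): predicting the mean scores exactly 0 and worse-than-mean models
score negative, which differs from squared correlation off-diagonal and is
therefore stated explicitly. Learners are pluggable `fit`/`predict` adapters;
ordinary least squares is built in, anything else (SVR, random forests) is
the caller's responsibility by design — this package validates and
aggregates, it does not model.

# The synthetic generators

**Permeability-like generator** (`generate_caco2_like`). Four molecular
properties with uniform marginals on plausible ranges — logD ∈ [−4, 6],
HCPSA ∈ [0, 150] Å², rgyr ∈ [2, 8] Å, frotb ∈ [0, 0.6] — and the endpoint
$\log P_{eff} = -4.358 + 0.317\min(\max(-1.8, \mathrm{logD}), 2.0)
- 0.00558\,\mathrm{HCPSA} - 0.179\,\mathrm{rgyr} + 1.074\,f_{rotb}
+ \mathcal N(0, \sigma^2)$.
logD and HCPSA are drawn from a Gaussian copula with correlation −0.8,
reflecting the real phenomenon that strongly polar compounds are
hydrophilic; that intercorrelation is what makes the 4→3D PCA embedding
near-lossless, and the suite asserts quality ≥ 0.95 on this generator. The
ranges are this package's choice (the source states none); they put the logD
clamp outside its linear window on an expected 62% of rows, so the generator
is deliberately *not* exactly linear — restricting `logD_range` to
[−1.8, 2] turns the clamp off, and then OLS recovers all five coefficients
to 1e-8 (a tested property). The default noise of 0.3 log units is a
realistic assay-scale error chosen once: it leaves a linear model in the
R² ≈ 0.5–0.9 regime rather than making the task trivial or hopeless.

**Fragment generator** (`generate_fragment_dataset`). Binary fragment
vectors from per-cluster Bernoulli profiles (characteristic fragments at
rate 0.85, background at 0.08), class labels from a median split of a random
linear score (emulating equal-frequency discretization of a potency value),
and planted activity cliffs: selected pairs get exactly equal fragment
vectors and opposite classes by copying one member's vector and flipping the
other's label. Defaults (n = 467, 97 fragments, 7 clusters) mirror the
dimensions of the inhibitor dataset this emulates.

What the generators do **not** emulate: real molecular structures (rows may
carry no SMILES), realistic fragment co-occurrence (real MACCS keys are
strongly hierarchical), measurement-error structure beyond i.i.d. Gaussian
noise, and class imbalance. A green test on synthetic data therefore
establishes algorithmic correctness and the qualitative phenomena (cliffs,
duplicate positions, clamp non-linearity), not toolkit-level agreement with
any particular published dataset — reproducing published per-dataset numbers
additionally depends on the SMARTS dialect of the matching toolkit and on
optimizer details, which is why fragment counts are documented as
toolkit-sensitive.

# Equal-frequency discretization and the frequency filter

The discretizer's threshold for class $c$ is the smallest data value $v$
with $\#\{x \le v\} \ge \lceil nc/k \rceil$; tied values always go with the
lower class. With distinct values and two classes this is a median split
assigning $\lceil n/2 \rceil$ compounds to the low class — e.g. 234 of 467 —
and with ties the class sizes deviate by exactly the tie count, which the
tests assert.

The fragment frequency filter keeps fragments matching at least `min_count`
(default 10) compounds and, by default, at most $n - \texttt{min\_count}$:
a fragment matching (almost) everything carries as little distance
information as one matching (almost) nothing. Because the underlying
description states only a minimum frequency, the upper cut is exposed as
`two_sided = FALSE` for one-sided behaviour.

# Known limitations

* No 3D conformer generation, structural alignment or depiction; structures
  exist for SMARTS matching and descriptors only.
* SMARTS dialects differ across toolkits; three MACCS keys are not
  expressible as single SMARTS in RDKit and are omitted by
  `maccs_smarts()` (returned as `NA` on request).
* The Sammon optimiser finds a local minimum; different parameterisations of
  the same distances may end at slightly different stress values. Determinism
  is guaranteed, global optimality is not.
* ANOVA on subset vs complement and χ² on subset vs whole dataset answer
  subtly different questions; rankings mixing numeric and nominal features
  inherit that asymmetry.
* The RDKit bridge spawns a Python process per call; for very large SMARTS ×
  compound workloads, batch the calls (one `match_fragments()` call matches
  the whole list at once).
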