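# chemspacemap

Chemical space mapping and visual validation of (Q)SAR models in R.

## The problem

(Q)SAR models predict biological activity from chemical structure, and
classical statistical validation compresses their performance into one or two
numbers. That tells you *how well* a model does, but not *where* it fails:
which compounds are misclassified together, whether the errors sit on
activity cliffs, whether the model is asked to extrapolate outside its
applicability domain. `chemspacemap` supports this kind of inspection for
cheminformaticians and QSAR modellers by mapping a small-molecule dataset
into 3D chemical space and attaching, per compound, every quantity one would
want to look at next to the map — as plain data frames, CSV files and static
plots rather than an interactive viewer.

## What it computes

- **Mapping.** Features are either numeric descriptors (standardized, then
  Euclidean distances) or binary structural fragments from SMARTS matching
  (Tanimoto distance `1 - |a∧b|/|a∨b|`). Compounds are clustered (k-means or
  hierarchical clustering, with silhouette-maximising automatic cluster-count
  selection) and embedded into 3D by PCA or Sammon's non-linear mapping,
  which minimises the stress
  `E = (Σδ_ij)⁻¹ Σ (δ_ij − d_ij)²/δ_ij` over 3D configurations.
- **Embedding quality.** Global quality is the Pearson correlation *r*
  between the n(n−1)/2 feature-space distance pairs and the 3D distance
  pairs (a warning below 0.6); per-compound embedding stress is
  `s_i = 1 − Pearson(δ_i·, d_i·)` ∈ [0, 2].
- **Subset specificity.** Features ranked by how specifically they
  characterise a cluster or compound against the whole dataset: χ²
  goodness-of-fit for nominal features, one-way ANOVA for numeric features,
  and a χ² on adaptively equal-width-binned data (initially 20 bins,
  decreasing until no bin is empty) for single compounds.
- **Activity cliffs.** The Structure-Activity Landscape Index
  `SALI_ij = |A_i − A_j| / (1 − sim_ij)` with per-compound mean/SD/max
  aggregates, plus exact detection of identical-feature pairs with opposite
  class (infinite SALI).
- **Applicability domains.** Centroid Euclidean distance (threshold 3× mean
  distance), leverage `h_ii = [X(XᵀX)⁻¹Xᵀ]_ii` with threshold `3(p+1)/n`, and
  mean k-NN distance (k = 3, threshold 3× mean).
- **Validation aggregation.** Leave-one-out and repeated k-fold
  cross-validation drivers with pluggable learners (OLS built in), and the
  aggregation rules for repeated predictions: mean value / RMSE for
  regression, active-ratio / error-ratio (and an always-misclassified flag)
  for binary endpoints, strict-majority-or-inconclusive for multi-class, and
  the inside-ratio for applicability-domain flags.

Structure-dependent steps (SMILES/SDF parsing, SMARTS substructure matching,
molecular descriptors) are delegated to RDKit through a bundled Python
bridge; `python` with the `rdkit` package must be on the PATH.

## Worked example

```r
library(chemspacemap)

ds <- generate_caco2_like(n = 100, noise_sd = 0.3, seed = 1)  # 4 properties + logPeff
cfg <- mapping_config("caco2-sim", dataset_hash(ds),
                      features = c("logD", "HCPSA", "rgyr", "frotb"),
                      clustering = list(name = "kmeans", k = 4),
                      embedding = "pca", seed = 1)
res <- run_pipeline(ds, cfg, compute_sali = TRUE, ad_method = "leverage")
res
#> <cs_mapping> 100 compounds | pca embedding | 4 clusters | r = 0.9877
```

`r = 0.9877` says the 3D map is a near-faithful picture of the 4-descriptor
space (4 correlated descriptors compress into 3 dimensions almost without
loss); no quality warning is logged. A leave-one-out cross-validation of the
built-in linear learner:

```r
tab <- loo_cross_validate(ds, "logPeff")
metrics(ds$features$logPeff, tab$predicted)
#> $r2   0.818
#> $rmse 0.356
```

The residual error is partly the generator's noise and partly the logD clamp
in the endpoint, which a linear model cannot represent. The strongest
activity cliff and what makes it special:

```r
worst <- which.max(res$coordinates$sali_mean)       # compound 50, mean SALI 4.01
head(rank_features(ds, worst), 2)
#>   feature        test            p
#> 1 logPeff binned-chi2 8.97e-06
#> 2    logD binned-chi2 2.87e-02
```

The cliff compound's endpoint value is the feature that most distinguishes it
from the dataset — its activity differs although its descriptors do not,
which is exactly what a SALI cliff means. `export_plot(res$coordinates,
inner = "logPeff", outer = "cluster", path = "map.png")` writes the dual-coded
3D scatter.

## Acceptance script

`scripts/acceptance.R` regenerates the package's reference quantity from
scratch — it simulates the permeability dataset with zero noise, verifies the
simulated endpoints against the generator's published formula, and evaluates
that formula at the origin of feature space — and writes the result as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Command line

A thin CLI over the same functions ships in `inst/cli/chemspacemap.R`
(subcommands `simulate`, `map`, `quality`, `specificity`, `sali`, `ad`,
`validate`, `plot`), e.g.:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","chemspacemap.R",package="chemspacemap"))')" \
  map --input data.csv --endpoint activity --distance euclidean --embed pca \
  --cluster auto --seed 7 -o mapping_out
```
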