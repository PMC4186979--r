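Package: chemspacemap
Title: Chemical Space Mapping and Visual Validation of QSAR Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps small-molecule datasets into 3D chemical space and quantifies
    how trustworthy that map and the models built on it are. Reads SD-Files and
    SMILES/feature CSVs, matches SMARTS fragment lists (e.g. MACCS-166) through
    RDKit, computes Euclidean and Tanimoto dissimilarities, embeds compounds
    with PCA or Sammon's non-linear mapping, and clusters them. On top of the
    map it provides a visual-validation toolbox: global embedding quality and
    per-compound embedding stress, feature-specificity ranking of compound
    subsets (chi-squared, ANOVA, adaptive binned chi-squared), SALI activity
    cliff detection including identical-feature conflicts, three applicability
    domain methods (centroid distance, leverage, k-nearest-neighbour), and
    aggregation of repeated cross-validation predictions per compound.
    Synthetic-data generators emulating a Caco-2-like regression dataset and a
    binary-fragment dataset with planted clusters and activity cliffs make
    every component testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: python3 with the rdkit package on PATH (used for SMARTS
    matching, descriptors and SDF interconversion)
Imports:
    cluster,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
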