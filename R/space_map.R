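#' Distance matrix container
#'
#' @param matrix Symmetric nonnegative n x n dissimilarity matrix with zero
#'   diagonal.
#' @param measure Measure name, `"euclidean"` or `"tanimoto"`.
#' @param features Names of the feature columns the distances were computed
#'   from (provenance).
#' @return An object of class `cs_distances`.
#' @export
cs_distances <- function(matrix, measure, features = character(0)) {
  stop_if_not_symmetric(matrix, "distance matrix")
  if (any(!is.finite(matrix))) stop("non-finite distances", call. = FALSE)
  if (any(matrix < -1e-12)) stop("negative distances", call. = FALSE)
  matrix[matrix < 0] <- 0
  diag(matrix) <- 0
  if (measure == "tanimoto" && any(matrix > 1 + 1e-12))
    stop("tanimoto distances must lie in [0, 1]", call. = FALSE)
  structure(list(matrix = matrix, measure = measure,
                 features = as.character(features)),
            class = "cs_distances")
}

#' @export
print.cs_distances <- function(x, ...) {
  cat("<cs_distances> ", nrow(x$matrix), " compounds, measure=", x$measure, "\n",
      sep = "")
  invisible(x)
}

#' Euclidean distances over standardized numeric features
#'
#' @param x A [cs_dataset] (its standardized numeric feature columns are used)
#'   or a numeric matrix.
#' @param columns Feature columns to use when `x` is a dataset.
#' @return A [cs_distances] with `measure = "euclidean"`.
#' @export
euclidean_distances <- function(x, columns = NULL) {
  if (inherits(x, "cs_dataset")) {
    m <- feature_matrix(x, columns)   # errors on missing values
    feats <- colnames(m)
  } else {
    m <- as.matrix(x)
    if (anyNA(m)) stop("missing values in feature matrix", call. = FALSE)
    feats <- colnames(m) %||% character(0)
  }
  cs_distances(euclid_full(m), "euclidean", feats)
}

#' Tanimoto distances over a binary fragment matrix
#'
#' Distance = 1 - |a AND b| / |a OR b|. Two all-zero fingerprints are treated
#' as identical (distance 0).
#'
#' @param fragments A [fragment_matrix] or binary 0/1 matrix.
#' @return A [cs_distances] with `measure = "tanimoto"`.
#' @export
tanimoto_distances <- function(fragments) {
  m <- if (inherits(fragments, "fragment_matrix")) fragments$matrix else as.matrix(fragments)
  if (!all(m %in% c(0, 1))) stop("non-binary entries in fragment matrix", call. = FALSE)
  storage.mode(m) <- "double"
  inter <- tcrossprod(m)                      # |a AND b|
  ones <- rowSums(m)
  union <- outer(ones, ones, "+") - inter     # |a OR b|
  sim <- ifelse(union == 0, 1, inter / pmax(union, 1))  # both empty => identical
  d <- 1 - sim
  d <- (d + t(d)) / 2
  diag(d) <- 0
  cs_distances(d, "tanimoto",
               if (inherits(fragments, "fragment_matrix")) fragments$smarts else character(0))
}

#' 3D embedding container
#'
#' @param coords n x 3 numeric coordinate matrix (columns x, y, z).
#' @param algorithm Algorithm name.
#' @param parameters List of algorithm parameters (provenance).
#' @param seed Seed used, if any.
#' @param stress Final stress for iterative embedders.
#' @param converged Convergence flag for iterative embedders.
#' @return An object of class `cs_embedding`.
#' @export
cs_embedding <- function(coords, algorithm, parameters = list(), seed = NULL,
                         stress = NA_real_, converged = NA) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("embedding must have 3 columns", call. = FALSE)
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  colnames(coords) <- c("x", "y", "z")
  structure(list(coords = coords, algorithm = algorithm, parameters = parameters,
                 seed = seed, stress = stress, converged = converged),
            class = "cs_embedding")
}

#' @export
print.cs_embedding <- function(x, ...) {
  cat("<cs_embedding> ", nrow(x$coords), " compounds, algorithm=", x$algorithm,
      if (!is.na(x$stress)) paste0(", stress=", signif(x$stress, 4)), "\n", sep = "")
  invisible(x)
}

#' PCA embedding into 3D
#'
#' Projects (standardized) numeric features onto the top three principal
#' components. Deterministic: each component's sign is fixed so that its
#' largest-magnitude loading is positive. If the data have fewer than three
#' informative dimensions the remaining coordinates are zero, so a dataset of
#' intrinsic dimension <= 3 is embedded losslessly (all pairwise distances
#' preserved).
#'
#' @param x A [cs_dataset] or numeric feature matrix.
#' @param columns Feature columns when `x` is a dataset.
#' @return A [cs_embedding] with `algorithm = "pca"`.
#' @export
embed_pca <- function(x, columns = NULL) {
  m <- if (inherits(x, "cs_dataset")) feature_matrix(x, columns) else as.matrix(x)
  if (nrow(m) < 3) stop("PCA embedding requires at least 3 compounds", call. = FALSE)
  centered <- sweep(m, 2, colMeans(m))
  sv <- svd(centered)
  k <- min(3, ncol(sv$v))
  coords <- matrix(0, nrow(m), 3)
  for (j in seq_len(k)) {
    load_j <- sv$v[, j]
    s <- sign(load_j[which.max(abs(load_j))])
    if (s == 0) s <- 1
    coords[, j] <- s * sv$u[, j] * sv$d[j]
  }
  cs_embedding(coords, "pca", parameters = list(features = colnames(m)))
}

#' Sammon non-linear mapping into 3D
#'
#' Minimises Sammon's stress
#' \deqn{E = \frac{1}{\sum_{i<j}\delta_{ij}} \sum_{i<j}
#'       \frac{(\delta_{ij}-d_{ij})^2}{\delta_{ij}}}
#' over 3D configurations, where \eqn{\delta} are the input dissimilarities and
#' \eqn{d} the embedded Euclidean distances. Pairs with \eqn{\delta_{ij}=0}
#' (identical compounds) are excluded from the sum: duplicates are collapsed to
#' one representative before optimisation and pinned to its coordinates
#' afterwards. The optimiser is Sammon's diagonal-Newton iteration (magic
#' factor 0.3) with step halving whenever a step would increase the stress;
#' initialisation is classical metric MDS (PCoA) of the distance matrix, so
#' the result is deterministic.
#'
#' @param distances A [cs_distances] (n >= 4).
#' @param max_iter Maximum iterations (default 500).
#' @param tol Convergence tolerance on the relative stress change
#'   (default 1e-9).
#' @param magic Sammon's step-size factor (default 0.3).
#' @param seed Unused by the deterministic optimiser; recorded for provenance.
#' @return A [cs_embedding] with the final `stress`, a `converged` flag, and
#'   the per-iteration stress trace in `parameters$stress_trace`.
#' @export
embed_sammon <- function(distances, max_iter = 500, tol = 1e-9, magic = 0.3,
                         seed = NULL) {
  stopifnot(inherits(distances, "cs_distances"))
  delta_full <- distances$matrix
  if (any(!is.finite(delta_full))) stop("non-finite distances", call. = FALSE)
  n_all <- nrow(delta_full)
  if (n_all < 4) stop("Sammon mapping requires at least 4 compounds", call. = FALSE)

  # Collapse zero-distance groups to representatives.
  groups <- zero_distance_groups(delta_full)
  reps <- vapply(groups, function(g) g[1], integer(1))
  delta <- delta_full[reps, reps, drop = FALSE]
  n <- length(reps)

  init <- classical_mds_3d(delta)
  if (n <= 3) {
    y <- init
    stress_trace <- sammon_stress(delta, euclid_full(y))
    converged <- TRUE
  } else {
    fit <- sammon_optimize(delta, init, max_iter, tol, magic)
    y <- fit$y
    stress_trace <- fit$trace
    converged <- fit$converged
  }
  if (!converged)
    warning("Sammon mapping did not converge within ", max_iter,
            " iterations; returning best configuration found")

  coords <- matrix(0, n_all, 3)
  for (gi in seq_along(groups)) coords[groups[[gi]], ] <- rep(y[gi, ], each = length(groups[[gi]]))
  cs_embedding(coords, "sammon",
               parameters = list(max_iter = max_iter, tol = tol, magic = magic,
                                 stress_trace = stress_trace,
                                 n_distinct = n),
               seed = seed,
               stress = stress_trace[length(stress_trace)],
               converged = converged)
}

# Transitive grouping of compounds whose pairwise dissimilarity is exactly 0.
zero_distance_groups <- function(delta) {
  n <- nrow(delta)
  parent <- uf_new(n)
  zero <- which(delta == 0 & upper.tri(delta), arr.ind = TRUE)
  for (r in seq_len(nrow(zero)))
    parent <- uf_union(parent, zero[r, 1], zero[r, 2])
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  unname(split(seq_len(n), roots))
}

# Classical metric MDS (PCoA) into exactly 3 columns, sign-fixed like embed_pca.
classical_mds_3d <- function(delta) {
  n <- nrow(delta)
  fit <- stats::cmdscale(stats::as.dist(delta), k = min(3, n - 1))
  coords <- matrix(0, n, 3)
  if (length(fit) > 0) {
    fit <- as.matrix(fit)
    for (j in seq_len(ncol(fit))) {
      s <- sign(fit[which.max(abs(fit[, j])), j])
      if (s == 0) s <- 1
      coords[, j] <- s * fit[, j]
    }
  }
  # break exact coincidences in the start configuration (division by d=0)
  dup <- duplicated(round(coords, 12))
  if (any(dup)) {
    shift <- max(1e-6, 1e-6 * max(abs(coords)))
    coords[dup, 1] <- coords[dup, 1] + shift * seq_len(sum(dup))
  }
  coords
}

sammon_stress <- function(delta, d) {
  keep <- delta > 0 & upper.tri(delta)
  sum((delta[keep] - d[keep])^2 / delta[keep]) / sum(delta[keep])
}

sammon_optimize <- function(delta, y, max_iter, tol, magic) {
  n <- nrow(delta)
  c_norm <- sum(delta[upper.tri(delta) & delta > 0])
  mask <- delta > 0
  diag(mask) <- FALSE
  eps <- .Machine$double.eps
  d <- euclid_full(y)
  stress <- sammon_stress(delta, d)
  trace <- stress
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d_safe <- pmax(d, eps)
    # first and (absolute) second partials of E wrt each coordinate
    w1 <- ifelse(mask, (delta - d_safe) / (delta * d_safe + !mask), 0)
    grad <- matrix(0, n, 3)
    hess <- matrix(0, n, 3)
    for (q in 1:3) {
      diffq <- outer(y[, q], y[, q], "-")
      grad[, q] <- (-2 / c_norm) * rowSums(w1 * diffq)
      h <- ifelse(mask,
                  ((delta - d_safe) -
                     (diffq^2 / d_safe) * (1 + (delta - d_safe) / d_safe)) /
                    (delta * d_safe + !mask),
                  0)
      hess[, q] <- (-2 / c_norm) * rowSums(h)
    }
    step <- grad / pmax(abs(hess), eps)
    # step halving: accept only stress-decreasing updates
    lambda <- magic
    improved <- FALSE
    for (half in 1:20) {
      y_new <- y - lambda * step
      d_new <- euclid_full(y_new)
      stress_new <- sammon_stress(delta, d_new)
      if (stress_new < stress) { improved <- TRUE; break }
      lambda <- lambda / 2
    }
    if (!improved) { converged <- TRUE; break }
    rel_change <- (stress - stress_new) / max(stress, eps)
    y <- y_new; d <- d_new; stress <- stress_new
    trace <- c(trace, stress)
    if (rel_change < tol || stress < 1e-12) { converged <- TRUE; break }
  }
  list(y = y, trace = trace, converged = converged)
}

#' Cluster a dataset
#'
#' Partitions compounds with k-means (coordinate input) or hierarchical
#' clustering with average or Ward linkage (distance input). `k = "auto"`
#' selects the number of clusters in `2..min(15, n - 1)` maximising the mean
#' silhouette width on the input distances. Deterministic for a given seed.
#'
#' @param x A [cs_dataset] / numeric matrix (k-means), or a [cs_distances]
#'   (hierarchical; also used for silhouette with k-means when supplied via
#'   `distances`).
#' @param method `"kmeans"`, `"hierarchical-average"` or `"hierarchical-ward"`.
#' @param k Number of clusters (>= 2) or `"auto"`.
#' @param seed Integer seed (k-means starts).
#' @param distances Optional [cs_distances] for silhouette evaluation when `x`
#'   is a coordinate matrix.
#' @param columns Feature columns when `x` is a dataset.
#' @return An object of class `cs_clustering`: list with integer `labels` in
#'   `1..k`, `k`, `method`, `parameters`.
#' @export
cluster_compounds <- function(x, method = c("kmeans", "hierarchical-average",
                                            "hierarchical-ward"),
                              k = "auto", seed = 1L, distances = NULL,
                              columns = NULL) {
  method <- match.arg(method)
  is_dist <- inherits(x, "cs_distances")
  if (is_dist && method == "kmeans")
    stop("k-means requires coordinate input, not a distance matrix", call. = FALSE)
  coords <- NULL
  if (!is_dist) {
    coords <- if (inherits(x, "cs_dataset")) feature_matrix(x, columns) else as.matrix(x)
    n <- nrow(coords)
  } else n <- nrow(x$matrix)
  dmat <- if (is_dist) x$matrix else
    if (!is.null(distances)) distances$matrix else euclid_full(coords)

  assign_k <- function(kk) {
    if (method == "kmeans") {
      fit <- with_seed(seed, stats::kmeans(coords, centers = kk, nstart = 10,
                                           iter.max = 100))
      fit$cluster
    } else {
      link <- if (method == "hierarchical-average") "average" else "ward.D2"
      stats::cutree(stats::hclust(stats::as.dist(dmat), method = link), k = kk)
    }
  }

  if (identical(k, "auto")) {
    ks <- 2:min(15, n - 1)
    if (length(ks) == 0) stop("too few compounds for auto clustering", call. = FALSE)
    sils <- vapply(ks, function(kk) {
      lab <- assign_k(kk)
      if (length(unique(lab)) < 2) return(-Inf)
      mean(cluster::silhouette(lab, stats::as.dist(dmat))[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sils)]
  } else {
    k <- as.integer(k)
    if (k < 2) stop("clusters must partition the dataset into >= 2 groups", call. = FALSE)
    if (k >= n) stop("k must be smaller than the number of compounds", call. = FALSE)
  }
  labels <- assign_k(k)
  labels <- match(labels, unique(labels))  # relabel 1..k in order of appearance
  structure(list(labels = as.integer(labels), k = as.integer(k), method = method,
                 parameters = list(seed = seed)),
            class = "cs_clustering")
}

#' @export
print.cs_clustering <- function(x, ...) {
  cat("<cs_clustering> ", length(x$labels), " compounds in ", x$k,
      " clusters (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Detect compounds with identical feature vectors
#'
#' Compounds with identical feature values are mapped to identical 3D
#' positions; this reports the partition into identical-feature groups and the
#' number of distinct vectors, and warns when that number is smaller than n.
#'
#' @param x Feature matrix, [fragment_matrix], or [cs_dataset].
#' @param columns Feature columns when `x` is a dataset.
#' @param warn Emit the duplicate-position warning (default `TRUE`)?
#' @return List with `groups` (list of integer index vectors), `n_distinct`,
#'   and `duplicated` (logical: belongs to a group of size > 1).
#' @export
detect_duplicate_positions <- function(x, columns = NULL, warn = TRUE) {
  m <- if (inherits(x, "fragment_matrix")) x$matrix
       else if (inherits(x, "cs_dataset")) feature_matrix(x, columns)
       else as.matrix(x)
  keys <- apply(m, 1, paste, collapse = "\r")
  groups <- unname(split(seq_len(nrow(m)), factor(keys, levels = unique(keys))))
  n_distinct <- length(groups)
  if (warn && n_distinct < nrow(m))
    warning(nrow(m), " compounds map to only ", n_distinct,
            " distinct positions due to identical feature values", call. = FALSE)
  sizes <- lengths(groups)
  dup <- rep(FALSE, nrow(m))
  for (g in groups[sizes > 1]) dup[g] <- TRUE
  list(groups = groups, n_distinct = n_distinct, duplicated = dup)
}
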