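#' SALI activity-cliff matrix
#'
#' The Structure-Activity Landscape Index for a pair of compounds is
#' `SALI_ij = |A_i - A_j| / (1 - sim_ij)`: a high value flags an activity
#' cliff (similar compounds, strongly differing activity). Pairs with
#' `sim_ij = 1` and differing activity have an infinite SALI and are flagged;
#' identical compounds with equal activity get SALI 0.
#'
#' @param activities Numeric activity vector; a nominal binary endpoint must be
#'   encoded 0/1 first (see [encode_binary()]).
#' @param similarities Symmetric n x n similarity matrix in `[0, 1]` with unit
#'   diagonal, e.g. `1 - tanimoto_distances(...)$matrix` for fragment features
#'   or [similarity_from_distances()] for numeric features.
#' @return An object of class `sali_profile`: list with the SALI `matrix`
#'   (`Inf` for flagged pairs, diagonal 0) and the inputs.
#' @export
sali_matrix <- function(activities, similarities) {
  activities <- as.numeric(activities)
  if (anyNA(activities)) stop("missing activity values", call. = FALSE)
  stop_if_not_symmetric(similarities, "similarity matrix")
  if (any(similarities < -1e-12 | similarities > 1 + 1e-12))
    stop("similarities must lie in [0, 1]", call. = FALSE)
  n <- length(activities)
  if (nrow(similarities) != n)
    stop("activities and similarity matrix disagree on n", call. = FALSE)
  dA <- abs(outer(activities, activities, "-"))
  denom <- 1 - similarities
  sali <- ifelse(denom == 0, ifelse(dA == 0, 0, Inf), dA / denom)
  diag(sali) <- 0
  structure(list(matrix = sali, activities = activities),
            class = "sali_profile")
}

#' @export
print.sali_profile <- function(x, ...) {
  n_inf <- sum(is.infinite(x$matrix)) / 2
  cat("<sali_profile> ", nrow(x$matrix), " compounds, ", n_inf,
      " identical-feature/different-activity pair(s)\n", sep = "")
  invisible(x)
}

#' Per-compound SALI aggregate features
#'
#' Transforms the pairwise SALI matrix into per-compound features: mean,
#' standard deviation and maximum over the finite off-diagonal entries of each
#' compound's row, plus the count of infinite (identical-feature,
#' different-activity) partners. Compounds sortable by any aggregate reveal
#' which ones form activity cliffs.
#'
#' @param profile A [sali_profile].
#' @return `data.frame` with columns `mean`, `sd`, `max`, `n_infinite`;
#'   aggregates are `NA` (flagged) for compounds without finite partners.
#' @export
sali_features <- function(profile) {
  stopifnot(inherits(profile, "sali_profile"))
  m <- profile$matrix
  n <- nrow(m)
  if (n < 2) stop("need at least 2 compounds", call. = FALSE)
  out <- data.frame(mean = rep(NA_real_, n), sd = NA_real_, max = NA_real_,
                    n_infinite = integer(n))
  for (i in seq_len(n)) {
    row <- m[i, -i]
    fin <- row[is.finite(row)]
    out$n_infinite[i] <- sum(is.infinite(row))
    if (length(fin) > 0) {
      out$mean[i] <- mean(fin)
      out$sd[i] <- if (length(fin) > 1) stats::sd(fin) else 0
      out$max[i] <- max(fin)
    }
  }
  out
}

#' Identical-feature compounds of opposite class
#'
#' Finds all compounds that share exactly equal feature vectors with at least
#' one other compound of the opposite (binary) class -- compounds that no model
#' using these features can separate, and exactly the pairs whose SALI is
#' flagged infinite under a similarity of 1.
#'
#' @param features Feature matrix, [fragment_matrix], or [cs_dataset].
#' @param classes Binary class vector (two levels, any encoding).
#' @param columns Feature columns when `features` is a dataset.
#' @return List with `compounds` (sorted integer indices) and `pairs`
#'   (two-column integer matrix of conflicting pairs, i < j).
#' @export
identical_feature_conflicts <- function(features, classes, columns = NULL) {
  m <- if (inherits(features, "fragment_matrix")) features$matrix
       else if (inherits(features, "cs_dataset")) feature_matrix(features, columns)
       else as.matrix(features)
  if (length(classes) != nrow(m))
    stop("classes and feature matrix disagree on n", call. = FALSE)
  lv <- unique(as.character(classes))
  if (length(lv) > 2) stop("binary endpoint required", call. = FALSE)
  cls <- as.character(classes)
  groups <- detect_duplicate_positions(m, warn = FALSE)$groups
  pairs <- matrix(integer(0), ncol = 2)
  for (g in groups[lengths(groups) > 1]) {
    for (a in seq_along(g)) for (b in seq_along(g)) {
      if (a < b && cls[g[a]] != cls[g[b]])
        pairs <- rbind(pairs, c(g[a], g[b]))
    }
  }
  colnames(pairs) <- c("i", "j")
  list(compounds = sort(unique(as.integer(pairs))), pairs = pairs)
}

#' Similarity matrix from numeric feature distances
#'
#' Converts a distance matrix to similarities via `sim = 1 - d / max(d)` --
#' this package's convention for applying SALI to numeric feature spaces
#' (fragment features should use Tanimoto similarity instead).
#'
#' @param distances A [cs_distances].
#' @return Symmetric similarity matrix in `[0, 1]` with unit diagonal.
#' @export
similarity_from_distances <- function(distances) {
  stopifnot(inherits(distances, "cs_distances"))
  d <- distances$matrix
  dmax <- max(d)
  if (dmax == 0) return(matrix(1, nrow(d), ncol(d)))
  1 - d / dmax
}

#' Encode a binary nominal endpoint as 0/1
#'
#' @param classes Vector with exactly two distinct values.
#' @param positive The value encoded as 1; default the first level in order of
#'   appearance.
#' @return Numeric 0/1 vector with attribute `positive`.
#' @export
encode_binary <- function(classes, positive = NULL) {
  cls <- as.character(classes)
  lv <- unique(cls)
  if (length(lv) != 2) stop("binary endpoint required (got ", length(lv),
                            " distinct values)", call. = FALSE)
  positive <- positive %||% lv[1]
  if (!positive %in% lv) stop("positive label '", positive, "' not present", call. = FALSE)
  structure(as.numeric(cls == positive), positive = positive)
}
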