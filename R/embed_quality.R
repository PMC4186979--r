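#' Global embedding quality
#'
#' Pearson product-moment correlation between the n(n-1)/2 feature-space
#' distance pairs and the corresponding 3D Euclidean distance pairs. The
#' quality ranges from 1 (perfect correlation) through 0 (none) to -1
#' (negative correlation); values below 0.6 correspond to moderate or weak
#' embedding quality and set the warning flag.
#'
#' @param feature_distances A [cs_distances] over the mapped features.
#' @param embedding A [cs_embedding] (or n x 3 coordinate matrix) for the same
#'   compounds.
#' @param warn_threshold Warning threshold on r (default 0.6).
#' @return List of class `quality_report`: `r`, `warning` (logical), and the
#'   per-compound `stress` vector when n >= 4 (else `NULL`).
#' @export
embedding_quality <- function(feature_distances, embedding, warn_threshold = 0.6) {
  stopifnot(inherits(feature_distances, "cs_distances"))
  coords <- if (inherits(embedding, "cs_embedding")) embedding$coords else as.matrix(embedding)
  n <- nrow(feature_distances$matrix)
  if (nrow(coords) != n) stop("embedding and distances disagree on n", call. = FALSE)
  if (n < 3) stop("embedding quality needs at least 3 compounds", call. = FALSE)
  fd <- lower_tri(feature_distances$matrix)
  ed <- lower_tri(euclid_full(coords))
  if (stats::sd(fd) == 0 || stats::sd(ed) == 0)
    stop("undefined correlation: a distance vector has zero variance", call. = FALSE)
  r <- stats::cor(fd, ed)
  stress <- if (n >= 4) embedding_stress(feature_distances, coords) else NULL
  structure(list(r = r, warning = r < warn_threshold, stress = stress),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report> embedding quality r = ", signif(x$r, 4), sep = "")
  if (x$warning) cat("  [WARNING: below 0.6 -- moderate or weak embedding]")
  cat("\n")
  if (!is.null(x$stress))
    cat("  per-compound stress: median ", signif(stats::median(x$stress), 3),
        ", max ", signif(max(x$stress), 3), "\n", sep = "")
  invisible(x)
}

#' Per-compound embedding stress
#'
#' Stress of compound i is `1 - Pearson(feature distances from i to all j != i,
#' 3D distances from i to all j != i)`, so values close to 0 mean the
#' compound's neighbourhood is faithfully embedded and values up to 2 mean the
#' distance ordering is inverted. A compound whose distance vector has zero
#' variance (e.g. a duplicate-heavy fragment space) gets stress 0 with its
#' index recorded in the `degenerate` attribute.
#'
#' @param feature_distances A [cs_distances].
#' @param embedding A [cs_embedding] or n x 3 coordinate matrix.
#' @return Numeric vector of length n in `[0, 2]` with attribute `degenerate`
#'   (integer indices of flagged compounds).
#' @export
embedding_stress <- function(feature_distances, embedding) {
  stopifnot(inherits(feature_distances, "cs_distances"))
  coords <- if (inherits(embedding, "cs_embedding")) embedding$coords else as.matrix(embedding)
  fd <- feature_distances$matrix
  n <- nrow(fd)
  if (n < 4) stop("per-compound stress needs at least 4 compounds (3 pairs)", call. = FALSE)
  ed <- euclid_full(coords)
  stress <- numeric(n)
  degenerate <- integer(0)
  for (i in seq_len(n)) {
    f <- fd[i, -i]
    e <- ed[i, -i]
    if (stats::sd(f) == 0 || stats::sd(e) == 0) {
      stress[i] <- 0
      degenerate <- c(degenerate, i)
    } else {
      stress[i] <- 1 - stats::cor(f, e)
    }
  }
  attr(stress, "degenerate") <- degenerate
  stress
}

#' Feature-space distance from every compound to one compound
#'
#' Returns row `index` of the feature-space distance matrix (self-distance 0),
#' usable as a highlightable dataset feature; the nearest neighbours of the
#' compound are the argsort of this vector.
#'
#' @param feature_distances A [cs_distances].
#' @param index Compound index (1-based).
#' @return Numeric vector of length n with attribute `nearest` (compound
#'   indices sorted by increasing distance, self excluded).
#' @export
distance_to_compound <- function(feature_distances, index) {
  stopifnot(inherits(feature_distances, "cs_distances"))
  n <- nrow(feature_distances$matrix)
  index <- as.integer(index)
  if (length(index) != 1 || is.na(index) || index < 1 || index > n)
    stop("compound index out of range (1..", n, ")", call. = FALSE)
  d <- feature_distances$matrix[index, ]
  nn <- setdiff(order(d), index)
  attr(d, "nearest") <- nn
  d
}
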