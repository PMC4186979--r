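#' Applicability domain result
#'
#' Common return type of the three AD methods: per-compound score (a distance
#' or a leverage), the decision threshold, and the inside flag
#' (`score <= threshold`).
#'
#' @param score Nonnegative per-compound scores.
#' @param threshold Decision threshold.
#' @param method Method name.
#' @param parameters List of method parameters.
#' @return `data.frame` of class `ad_result` with columns `score`, `inside`;
#'   attributes `threshold`, `method`, `parameters`.
#' @keywords internal
ad_result <- function(score, threshold, method, parameters) {
  out <- data.frame(score = as.numeric(score), inside = score <= threshold)
  attr(out, "threshold") <- threshold
  attr(out, "method") <- method
  attr(out, "parameters") <- parameters
  class(out) <- c("ad_result", "data.frame")
  out
}

#' @export
print.ad_result <- function(x, ...) {
  cat("<ad_result> method=", attr(x, "method"), ", threshold=",
      signif(attr(x, "threshold"), 4), ": ", sum(x$inside), "/", nrow(x),
      " compounds inside\n", sep = "")
  invisible(x)
}

#' Centroid-distance applicability domain
#'
#' Score = Euclidean distance from each compound to the dataset centroid (a
#' virtual compound with mean feature values); threshold = `factor` times the
#' mean of these distances (default factor 3). Features should be standardized
#' first so that no single descriptor dominates. Its known weakness: outliers
#' extreme in a single correlated feature are often not excluded (use
#' [ad_leverage()]), and whole groups of mutually similar outliers are excluded
#' together (use [ad_knn()]).
#'
#' @param features Standardized numeric matrix or [cs_dataset].
#' @param factor Threshold multiplier (> 0, default 3).
#' @param columns Feature columns when a dataset is given.
#' @return An `ad_result`.
#' @export
ad_centroid <- function(features, factor = 3, columns = NULL) {
  if (factor <= 0) stop("factor must be positive", call. = FALSE)
  m <- if (inherits(features, "cs_dataset")) feature_matrix(features, columns)
       else as.matrix(features)
  if (nrow(m) < 2) stop("need at least 2 compounds", call. = FALSE)
  if (anyNA(m)) stop("missing values in feature matrix", call. = FALSE)
  centroid <- colMeans(m)
  score <- sqrt(rowSums(sweep(m, 2, centroid)^2))
  ad_result(score, factor * mean(score), "centroid", list(factor = factor))
}

#' Leverage applicability domain
#'
#' Score = leverage `h_ii`, the diagonal of the hat matrix
#' `X (X'X)^-1 X'` with design matrix `X = [1 | features]`; threshold =
#' `factor * (p + 1) / n` (the conventional `h* = 3 p~ / n` with `p~` model
#' parameters). Unlike the centroid distance, leverage accounts for feature
#' covariance, so a compound extreme in one correlated feature is excluded. It
#' is invariant to invertible affine transforms of the feature columns, so no
#' standardization is needed.
#'
#' @param features Numeric matrix or [cs_dataset] (n > p + 1, full column
#'   rank).
#' @param factor Threshold multiplier (default 3).
#' @param columns Feature columns when a dataset is given.
#' @return An `ad_result` (scores in `[0, 1]`).
#' @export
ad_leverage <- function(features, factor = 3, columns = NULL) {
  if (factor <= 0) stop("factor must be positive", call. = FALSE)
  m <- if (inherits(features, "cs_dataset")) feature_matrix(features, columns)
       else as.matrix(features)
  if (anyNA(m)) stop("missing values in feature matrix", call. = FALSE)
  n <- nrow(m); p <- ncol(m)
  if (n <= p + 1)
    stop("leverage needs n > p + 1 (n = ", n, ", p = ", p, ")", call. = FALSE)
  X <- cbind(1, m)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("rank-deficient design matrix: remove collinear or constant features",
         call. = FALSE)
  Q <- qr.Q(qr_x)
  h <- rowSums(Q^2)
  ad_result(h, factor * (p + 1) / n, "leverage", list(factor = factor))
}

#' k-nearest-neighbour applicability domain
#'
#' Score = mean Euclidean distance from each compound to its `k` nearest
#' neighbours (self excluded, ties at the k-th neighbour broken by compound
#' index); threshold = `factor` times the mean score over all compounds
#' (defaults k = 3, factor 3). Tolerates clusters of mutually similar
#' compounds far from the bulk -- only genuinely isolated compounds are
#' excluded.
#'
#' @param features Standardized numeric matrix or [cs_dataset] (n > k).
#' @param k Number of neighbours (default 3).
#' @param factor Threshold multiplier (default 3).
#' @param columns Feature columns when a dataset is given.
#' @return An `ad_result`.
#' @export
ad_knn <- function(features, k = 3, factor = 3, columns = NULL) {
  if (factor <= 0) stop("factor must be positive", call. = FALSE)
  m <- if (inherits(features, "cs_dataset")) feature_matrix(features, columns)
       else as.matrix(features)
  if (anyNA(m)) stop("missing values in feature matrix", call. = FALSE)
  n <- nrow(m)
  k <- as.integer(k)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n", call. = FALSE)
  d <- euclid_full(m)
  score <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(d[i, others], others)]  # index-tie-break: determinism
    mean(d[i, ord[seq_len(k)]])
  }, numeric(1))
  ad_result(score, factor * mean(score), "knn", list(k = k, factor = factor))
}
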