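#' Feature specificity of a compound subset
#'
#' @description
#' How specifically does each feature characterise a selected subset (a
#' cluster, a pair of neighbours, or a single compound) against the whole
#' dataset? Each feature is scored with a statistical test and features are
#' ranked ascending by p-value: low p means the subset's value distribution
#' differs from the dataset's.
#'
#' Routing: nominal features use a chi-squared goodness-of-fit test of the
#' subset's category counts against expectations from whole-dataset
#' proportions; numeric features with subset size >= 2 use one-way ANOVA of
#' subset vs complement; a numeric feature of a single compound uses the
#' chi-squared test on adaptively binned data.
#'
#' @name subgroup-specificity
NULL

#' Chi-squared specificity of a nominal feature
#'
#' Goodness-of-fit test: observed = subset category counts, expected =
#' whole-dataset category proportions scaled to the subset size; p-value from
#' the chi-squared distribution with (categories - 1) degrees of freedom.
#' Expected counts below 1 are tolerated (exploratory use) but flagged.
#'
#' @param values Character/factor vector over the whole dataset.
#' @param subset Integer indices of the selected compounds (non-empty).
#' @return p-value in (0, 1] with attributes `statistic`, `df`, `flag`
#'   (`"degenerate"` for a single-category feature, `"low-expected"` when any
#'   expected count < 1, else `NA`).
#' @export
nominal_specificity <- function(values, subset) {
  subset <- check_subset(subset, length(values))
  values <- as.character(values)
  cats <- unique(values[!is.na(values)])
  if (length(cats) < 2)
    return(structure(1, statistic = 0, df = 0, flag = "degenerate"))
  obs <- vapply(cats, function(cl) sum(values[subset] == cl, na.rm = TRUE), numeric(1))
  prop <- vapply(cats, function(cl) mean(values == cl, na.rm = TRUE), numeric(1))
  expd <- prop * length(subset)
  stat <- sum((obs - expd)^2 / expd)
  df <- length(cats) - 1
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(max(p, .Machine$double.xmin), statistic = stat, df = df,
            flag = if (any(expd < 1)) "low-expected" else NA_character_)
}

#' ANOVA specificity of a numeric feature
#'
#' One-way analysis of variance between the subset and its complement (two
#' groups; disjoint groups are required by the test, hence complement rather
#' than whole dataset). Subsets of a single compound are routed to
#' [single_compound_specificity()].
#'
#' @param values Numeric vector over the whole dataset.
#' @param subset Integer indices of the selected compounds.
#' @return p-value in (0, 1] with attributes `statistic` (F), `df`, `flag`.
#' @export
numeric_specificity <- function(values, subset) {
  subset <- check_subset(subset, length(values))
  values <- as.numeric(values)
  if (length(subset) < 2)
    return(single_compound_specificity(values, subset))
  comp <- setdiff(seq_along(values), subset)
  if (length(comp) < 2)
    stop("complement must contain at least 2 compounds", call. = FALSE)
  g1 <- values[subset]; g2 <- values[comp]
  n1 <- length(g1); n2 <- length(g2); n <- n1 + n2
  gm <- mean(c(g1, g2))
  ss_between <- n1 * (mean(g1) - gm)^2 + n2 * (mean(g2) - gm)^2
  ss_within <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  df1 <- 1; df2 <- n - 2
  if (ss_within == 0) {
    if (ss_between == 0)
      return(structure(1, statistic = 0, df = c(df1, df2), flag = "degenerate"))
    return(structure(.Machine$double.xmin, statistic = Inf, df = c(df1, df2),
                     flag = "zero-within-variance"))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(max(p, .Machine$double.xmin), statistic = f, df = c(df1, df2),
            flag = NA_character_)
}

#' Adaptive equal-width binning
#'
#' Equal-width binning starting from `initial_bins` intervals over
#' `[min, max]`; whenever any interval is empty the number of intervals is
#' decreased by one and the binning reapplied, until no empty bins exist.
#' Returns the edges for the largest such bin count. The last bin is closed,
#' all others are half-open (a value exactly on an interior edge falls in the
#' right bin).
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @param initial_bins Starting bin count (default 20).
#' @return Numeric vector of `k + 1` bin edges with attribute `k`.
#' @export
adaptive_equal_width_bins <- function(values, initial_bins = 20) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("missing values not allowed", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) stop("all values identical: cannot bin", call. = FALSE)
  for (k in seq(from = max(2, initial_bins), to = 2)) {
    edges <- seq(rng[1], rng[2], length.out = k + 1)
    counts <- tabulate(bin_index(values, edges), nbins = k)
    if (all(counts > 0)) return(structure(edges, k = k))
  }
  # k = 2 always has occupied end bins (min and max are distinct)
  stop("binning failed", call. = FALSE)  # nocov
}

# Half-open bins [e_i, e_{i+1}), last bin closed.
bin_index <- function(values, edges) {
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), length(edges) - 1L)
}

#' Binned chi-squared specificity of a single compound
#'
#' ANOVA is not applicable to a single compound, so the numeric feature is
#' binned with [adaptive_equal_width_bins()] and a chi-squared goodness-of-fit
#' test compares the compound's one-hot bin membership against the dataset's
#' bin proportions: a compound alone in an extreme bin scores a much lower
#' p-value than one sitting in the most populated bin.
#'
#' @param values Numeric vector over the whole dataset.
#' @param index Index of the single compound (length-1 subset).
#' @param initial_bins Starting bin count for the adaptive binning.
#' @return p-value in (0, 1] with attributes as in [nominal_specificity()].
#' @export
single_compound_specificity <- function(values, index, initial_bins = 20) {
  index <- check_subset(index, length(values))
  if (length(index) != 1) stop("exactly one compound index required", call. = FALSE)
  values <- as.numeric(values)
  if (length(unique(values)) < 2)
    return(structure(1, statistic = 0, df = 0, flag = "degenerate"))
  edges <- adaptive_equal_width_bins(values, initial_bins)
  k <- attr(edges, "k")
  bins <- bin_index(values, edges)
  prop <- tabulate(bins, nbins = k) / length(values)
  obs <- as.numeric(seq_len(k) == bins[index])
  stat <- sum((obs - prop)^2 / prop)
  df <- k - 1
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(max(p, .Machine$double.xmin), statistic = stat, df = df,
            flag = if (any(prop * 1 < 1)) "low-expected" else NA_character_)
}

#' Rank all features by subset specificity
#'
#' Every feature gets exactly one p-value through the test router (nominal ->
#' chi-squared; numeric with subset size >= 2 -> ANOVA; numeric single
#' compound -> binned chi-squared) and the features are sorted ascending by
#' p-value with a stable sort (ties keep the input feature order). A
#' Bonferroni-adjusted column is included for information only; the ranking
#' itself is exploratory and unadjusted.
#'
#' @param dataset A [cs_dataset].
#' @param subset Integer indices of the selected compounds.
#' @param columns Feature columns to rank; default all (including endpoints,
#'   which is often informative when inspecting clusters).
#' @return A `data.frame` of class `specificity_ranking` with columns
#'   `feature`, `test`, `p`, `p_bonferroni`, `flag`.
#' @export
rank_features <- function(dataset, subset, columns = NULL) {
  stopifnot(inherits(dataset, "cs_dataset"))
  subset <- check_subset(subset, n_compounds(dataset), allow_full = TRUE)
  columns <- columns %||% names(dataset$features)
  full <- length(subset) >= n_compounds(dataset)
  rows <- lapply(columns, function(col) {
    vals <- dataset$features[[col]]
    if (full) {  # selecting everything distinguishes nothing
      p <- structure(1, flag = "degenerate")
      test <- if (dataset$feature_types[[col]] == "nominal") "chi2" else "anova"
    } else if (dataset$feature_types[[col]] == "nominal") {
      p <- nominal_specificity(vals, subset)
      test <- "chi2"
    } else if (length(subset) >= 2 &&
               length(subset) <= length(vals) - 2) {
      p <- numeric_specificity(vals, subset)
      test <- "anova"
    } else if (length(subset) == 1) {
      p <- single_compound_specificity(vals, subset)
      test <- "binned-chi2"
    } else {  # subset = (almost) everything: no meaningful complement
      p <- structure(1, flag = "degenerate")
      test <- "anova"
    }
    data.frame(feature = col, test = test, p = as.numeric(p),
               flag = attr(p, "flag") %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out <- out[order(out$p), c("feature", "test", "p", "p_bonferroni", "flag")]
  rownames(out) <- NULL
  class(out) <- c("specificity_ranking", "data.frame")
  out
}

check_subset <- function(subset, n, allow_full = FALSE) {
  subset <- as.integer(subset)
  if (length(subset) == 0) stop("subset must be non-empty", call. = FALSE)
  if (anyNA(subset) || any(subset < 1) || any(subset > n))
    stop("subset indices out of range (1..", n, ")", call. = FALSE)
  subset <- unique(subset)
  if (!allow_full && length(subset) >= n)
    stop("subset must be a proper subset of the dataset", call. = FALSE)
  subset
}
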