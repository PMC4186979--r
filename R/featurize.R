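#' Structural fragment feature matrix
#'
#' Binary compounds-x-fragments matrix produced by SMARTS substructure
#' matching; entry (i, j) is 1 iff fragment j matches compound i at least once.
#'
#' @param matrix Binary integer matrix (compounds x fragments).
#' @param smarts Character vector of fragment SMARTS (no duplicates), one per
#'   column.
#' @return An object of class `fragment_matrix` with fields `matrix`, `smarts`
#'   and per-fragment `counts` (column sums).
#' @export
fragment_matrix <- function(matrix, smarts) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  if (!all(matrix %in% c(0L, 1L)))
    stop("fragment matrix entries must be 0/1", call. = FALSE)
  smarts <- as.character(smarts)
  if (length(smarts) != ncol(matrix))
    stop("one SMARTS per column required", call. = FALSE)
  if (anyDuplicated(smarts))
    stop("duplicate SMARTS in fragment list: ",
         paste(unique(smarts[duplicated(smarts)]), collapse = ", "), call. = FALSE)
  colnames(matrix) <- smarts
  structure(list(matrix = matrix, smarts = smarts, counts = colSums(matrix)),
            class = "fragment_matrix")
}

#' @export
print.fragment_matrix <- function(x, ...) {
  cat("<fragment_matrix> ", nrow(x$matrix), " compounds x ", length(x$smarts),
      " fragments (", sum(x$counts > 0), " with >=1 match)\n", sep = "")
  invisible(x)
}

#' Match a SMARTS fragment list against a dataset
#'
#' Runs RDKit substructure matching of each SMARTS pattern against each
#' compound structure.
#'
#' @param dataset A [cs_dataset] whose compounds all carry structures.
#' @param smarts_list Character vector of SMARTS patterns (e.g. from
#'   [maccs_smarts()] or [read_smarts_list()]).
#' @return A [fragment_matrix].
#' @export
match_fragments <- function(dataset, smarts_list) {
  stopifnot(inherits(dataset, "cs_dataset"))
  smiles <- dataset$compounds$smiles
  if (anyNA(smiles))
    stop("compound(s) without structure: ",
         paste(which(is.na(smiles)), collapse = ", "), call. = FALSE)
  smarts_list <- as.character(smarts_list)
  if (length(smarts_list) == 0) stop("empty SMARTS list", call. = FALSE)
  resp <- chem_bridge("match_smarts", smiles = as.list(smiles),
                      smarts = as.list(smarts_list))
  m <- resp$matrix
  if (is.list(m)) m <- do.call(rbind, m)
  m <- matrix(as.integer(m), nrow = n_compounds(dataset),
              ncol = length(smarts_list))
  fragment_matrix(m, smarts_list)
}

#' The MACCS 166-key SMARTS list
#'
#' Retrieves the 166 MACCS structural-key SMARTS patterns from RDKit at run
#' time. Three keys (1, 125, 166) are not expressible as a single SMARTS and
#' are dropped unless `keep_placeholders = TRUE` (then returned as `NA`).
#' Note that SMARTS dialects differ between toolkits, so matched-fragment
#' counts are toolkit-sensitive.
#'
#' @param keep_placeholders Keep inexpressible keys as `NA` entries?
#' @return Named character vector of SMARTS (`maccs_001` ... `maccs_166`).
#' @export
maccs_smarts <- function(keep_placeholders = FALSE) {
  resp <- chem_bridge("maccs_smarts")
  pats <- resp$smarts
  pats <- vapply(pats, function(p) if (is.null(p)) NA_character_ else p, character(1))
  names(pats) <- sprintf("maccs_%03d", seq_along(pats))
  if (!keep_placeholders) pats <- pats[!is.na(pats)]
  pats
}

#' Read a SMARTS list file
#'
#' Plain text, one SMARTS per line; `#` starts a comment; blank lines ignored.
#'
#' @param path File path.
#' @return Character vector of SMARTS.
#' @export
read_smarts_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Filter fragments by match frequency
#'
#' Drops uninformative fragment columns: those matching fewer than `min_count`
#' compounds and (two-sided, the default) those matching more than
#' `n - min_count` compounds — a near-constant column carries no distance
#' information. Column order is preserved; the operation is idempotent.
#'
#' @param fragments A [fragment_matrix].
#' @param min_count Minimum match count (default 10).
#' @param two_sided Also drop columns with more than `n - min_count` matches?
#' @return A filtered [fragment_matrix].
#' @export
filter_min_frequency <- function(fragments, min_count = 10, two_sided = TRUE) {
  stopifnot(inherits(fragments, "fragment_matrix"), min_count >= 1)
  n <- nrow(fragments$matrix)
  keep <- fragments$counts >= min_count
  if (two_sided) keep <- keep & fragments$counts <= (n - min_count)
  if (!any(keep)) stop("no informative features: all ", length(keep),
                       " fragments filtered out", call. = FALSE)
  fragment_matrix(fragments$matrix[, keep, drop = FALSE], fragments$smarts[keep])
}

#' Equal-frequency discretization of a numeric endpoint
#'
#' Splits a numeric vector into `n_classes` classes of (near-)equal size. The
#' threshold for class c is the smallest data value v such that
#' `#{x <= v} >= ceiling(n * c / n_classes)`; tied values always go with the
#' lower class, so class sizes differ from n/k by at most the number of ties at
#' each threshold. With `low_is_active` (binary case), values `<=` the first
#' threshold are labelled `"active"`.
#'
#' @param values Numeric vector without missing values.
#' @param n_classes Number of classes (default 2).
#' @param low_is_active For 2 classes: label the low side `"active"` (default
#'   `TRUE`; e.g. low IC50 = potent inhibitor).
#' @return List with `classes` (character vector) and `thresholds` (numeric,
#'   length `n_classes - 1`, monotone increasing).
#' @export
discretize_equal_frequency <- function(values, n_classes = 2, low_is_active = TRUE) {
  if (anyNA(values)) stop("missing values not allowed", call. = FALSE)
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  n <- length(values)
  distinct <- sort(unique(values))
  if (length(distinct) < n_classes)
    stop("fewer distinct values (", length(distinct), ") than classes (",
         n_classes, ")", call. = FALSE)
  cum <- vapply(distinct, function(v) sum(values <= v), numeric(1))
  thresholds <- vapply(seq_len(n_classes - 1), function(cl) {
    target <- ceiling(n * cl / n_classes)
    distinct[which(cum >= target)[1]]
  }, numeric(1))
  if (any(diff(thresholds) < 0)) stop("thresholds not monotone", call. = FALSE)
  # class index = 1 + number of thresholds strictly below the value
  idx <- 1L + vapply(values, function(x) sum(x > thresholds), integer(1))
  labels <- if (n_classes == 2) {
    if (low_is_active) c("active", "inactive") else c("inactive", "active")
  } else paste0("class", seq_len(n_classes))
  list(classes = labels[idx], thresholds = thresholds)
}

#' Standardize numeric feature columns
#'
#' Centres each named column to mean 0 and scales to unit population variance
#' (denominator n). The original mean/SD of each column is stored in the
#' dataset's `standardization` field for inverse mapping. Required before
#' mixing descriptors of different scales in Euclidean distances.
#'
#' @param dataset A [cs_dataset].
#' @param columns Numeric feature columns; default all non-endpoint numeric
#'   columns.
#' @return The dataset with standardized columns.
#' @export
standardize_numeric <- function(dataset, columns = NULL) {
  stopifnot(inherits(dataset, "cs_dataset"))
  if (is.null(columns)) {
    columns <- feature_names(dataset)
    columns <- columns[dataset$feature_types[columns] == "numeric"]
  }
  m <- feature_matrix(dataset, columns)
  n <- nrow(m)
  mu <- colMeans(m)
  sigma <- sqrt(colMeans(sweep(m, 2, mu)^2))  # population SD
  const <- sigma == 0
  if (any(const))
    stop("constant feature column(s): ", paste(columns[const], collapse = ", "),
         call. = FALSE)
  scaled <- sweep(sweep(m, 2, mu), 2, sigma, "/")
  for (j in seq_along(columns)) dataset$features[[columns[j]]] <- scaled[, j]
  dataset$standardization <- c(dataset$standardization %||% list(),
                               stats::setNames(Map(function(m, s) list(mean = m, sd = s),
                                                   mu, sigma), columns))
  dataset
}

#' Compute molecular descriptors via RDKit
#'
#' Appends numeric descriptor columns computed by the toolkit (not
#' reimplemented). Available descriptors: `mw` (molecular weight), `logp`
#' (Crippen octanol/water partition coefficient), `tpsa` (topological polar
#' surface area), `nbonds` (heavy-atom bond count), `mr` (Crippen molar
#' refractivity).
#'
#' @param dataset A [cs_dataset] with structures.
#' @param descriptors Character vector of descriptor names.
#' @return The dataset with appended numeric columns named after the
#'   descriptors.
#' @export
compute_descriptors <- function(dataset,
                                descriptors = c("mw", "logp", "tpsa", "nbonds", "mr")) {
  stopifnot(inherits(dataset, "cs_dataset"))
  smiles <- dataset$compounds$smiles
  if (anyNA(smiles))
    stop("compound(s) without structure: ",
         paste(which(is.na(smiles)), collapse = ", "), call. = FALSE)
  resp <- chem_bridge("descriptors", smiles = as.list(smiles),
                      names = as.list(as.character(descriptors)))
  for (nm in descriptors) {
    dataset$features[[nm]] <- as.numeric(resp$values[[nm]])
    dataset$feature_types[[nm]] <- "numeric"
  }
  dataset
}
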