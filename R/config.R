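#' Mapping configuration
#'
#' A `mapping_config` captures everything needed to reproduce a chemical-space
#' mapping exactly: the dataset identity (id + content hash), the selected
#' feature columns, the distance measure, the clustering and embedding
#' algorithms with their parameters, and the random seed for any randomised
#' step. Two runs from the same configuration and dataset produce identical
#' cluster assignments and 3D coordinates.
#'
#' @param dataset_id Free-text dataset identifier (e.g. file name).
#' @param dataset_hash Content hash from [dataset_hash()] (may be `NA` before
#'   the dataset is known).
#' @param features Character vector of feature columns used for mapping.
#' @param distance Distance measure: list with `name` (`"euclidean"` or
#'   `"tanimoto"`) and optional parameters.
#' @param clustering List with `name` (`"kmeans"`, `"hierarchical-average"`,
#'   `"hierarchical-ward"`) and parameters (e.g. `k`, possibly `"auto"`).
#' @param embedding List with `name` (`"pca"` or `"sammon"`) and parameters.
#' @param seed Integer random seed; required.
#' @return An object of class `mapping_config`.
#' @export
mapping_config <- function(dataset_id, dataset_hash = NA_character_, features,
                           distance = list(name = "euclidean"),
                           clustering = list(name = "kmeans", k = "auto"),
                           embedding = list(name = "pca"),
                           seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a finite integer seed is required", call. = FALSE)
  norm_alg <- function(x, what) {
    if (is.character(x)) x <- list(name = x)
    if (!is.list(x) || is.null(x$name))
      stop(what, " must be a list with a 'name' field", call. = FALSE)
    x
  }
  structure(list(
    schema_version = 1L,
    dataset_id = as.character(dataset_id),
    dataset_hash = as.character(dataset_hash),
    features = as.character(features),
    distance = norm_alg(distance, "distance"),
    clustering = norm_alg(clustering, "clustering"),
    embedding = norm_alg(embedding, "embedding"),
    seed = as.integer(seed)
  ), class = "mapping_config")
}

#' @export
print.mapping_config <- function(x, ...) {
  cat("<mapping_config v", x$schema_version, "> dataset=", x$dataset_id,
      " | ", length(x$features), " features | distance=", x$distance$name,
      " | clustering=", x$clustering$name, " | embedding=", x$embedding$name,
      " | seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Save / load a mapping configuration
#'
#' Configurations are persisted as human-diffable JSON with a schema-version
#' field, so a mapping can be stored to a file and shared; reloading yields a
#' field-by-field identical configuration.
#'
#' @param config A [mapping_config].
#' @param path JSON file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns the
#'   [mapping_config].
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "mapping_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("truncated or invalid config file: ",
                                           conditionMessage(e), call. = FALSE))
  required <- c("schema_version", "dataset_id", "features", "distance",
                "clustering", "embedding", "seed")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("config file is missing required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!identical(as.integer(raw$schema_version), 1L))
    stop("incompatible config schema version: ", raw$schema_version,
         " (this package reads version 1)", call. = FALSE)
  mapping_config(dataset_id = raw$dataset_id,
                 dataset_hash = raw$dataset_hash %||% NA_character_,
                 features = raw$features,
                 distance = as.list(raw$distance),
                 clustering = as.list(raw$clustering),
                 embedding = as.list(raw$embedding),
                 seed = raw$seed)
}
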