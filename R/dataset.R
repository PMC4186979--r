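#' Compound dataset container
#'
#' A `cs_dataset` holds an ordered collection of compounds (structures as
#' SMILES, stable 1-based index, optional names), a feature table with one
#' typed column per feature (numeric or nominal), and zero or more columns
#' designated as endpoints. Endpoint columns live in the feature table but are
#' flagged so that mapping operations exclude them: endpoint values belong to
#' the dataset, not to the embedding.
#'
#' @param smiles Character vector of SMILES (may contain `NA` for synthetic
#'   rows without structures), or `NULL` for a structure-free dataset.
#' @param features `data.frame` of per-compound feature values.
#' @param feature_types Named character vector mapping feature names to
#'   `"numeric"` or `"nominal"`; inferred when `NULL` (columns whose values all
#'   parse as numbers become numeric).
#' @param endpoints Character vector of feature-table column names flagged as
#'   endpoints (excluded from embedding).
#' @param names Optional compound names.
#' @return An object of class `cs_dataset`.
#' @export
cs_dataset <- function(smiles = NULL, features = data.frame(), feature_types = NULL,
                       endpoints = character(0), names = NULL) {
  features <- as.data.frame(features, check.names = FALSE, stringsAsFactors = FALSE)
  n <- if (!is.null(smiles)) length(smiles) else nrow(features)
  if (n == 0) stop("empty dataset: no compounds", call. = FALSE)
  if (is.null(smiles)) smiles <- rep(NA_character_, n)
  if (nrow(features) == 0 && ncol(features) == 0)
    features <- data.frame(row.names = seq_len(n))
  if (nrow(features) != n)
    stop("feature table has ", nrow(features), " rows but there are ", n,
         " compounds", call. = FALSE)
  if (anyDuplicated(names(features)))
    stop("duplicate feature column names: ",
         paste(unique(names(features)[duplicated(names(features))]), collapse = ", "),
         call. = FALSE)

  feature_types <- infer_feature_types(features, feature_types)
  for (col in names(features)) {
    features[[col]] <- if (feature_types[[col]] == "numeric")
      as.numeric(features[[col]]) else as.character(features[[col]])
  }
  if (!all(endpoints %in% names(features)))
    stop("endpoint column(s) not in feature table: ",
         paste(setdiff(endpoints, names(features)), collapse = ", "), call. = FALSE)

  structure(list(
    compounds = data.frame(index = seq_len(n),
                           name = as.character(names %||% rep(NA_character_, n)),
                           smiles = as.character(smiles),
                           stringsAsFactors = FALSE),
    features = features,
    feature_types = feature_types,
    endpoints = as.character(endpoints)
  ), class = "cs_dataset")
}

# One declared type per column; "all values parse as numbers" => numeric.
infer_feature_types <- function(features, override = NULL) {
  types <- vapply(features, function(col) {
    if (is.numeric(col)) return("numeric")
    vals <- trimws(as.character(col))
    vals <- vals[!is.na(vals) & nzchar(vals)]
    if (length(vals) > 0 &&
        all(!is.na(suppressWarnings(as.numeric(vals))))) "numeric" else "nominal"
  }, character(1))
  if (!is.null(override)) {
    bad <- setdiff(names(override), names(features))
    if (length(bad)) stop("type override for unknown column(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (!all(override %in% c("numeric", "nominal")))
      stop("feature types must be 'numeric' or 'nominal'", call. = FALSE)
    types[names(override)] <- override
  }
  types
}

#' @export
print.cs_dataset <- function(x, ...) {
  nf <- length(x$feature_types)
  cat("<cs_dataset> ", nrow(x$compounds), " compounds, ", nf, " feature column(s)",
      if (length(x$endpoints)) paste0(" (", length(x$endpoints), " endpoint)"), "\n",
      sep = "")
  if (nf > 0) {
    tp <- table(factor(x$feature_types, levels = c("numeric", "nominal")))
    cat("  types: ", tp[["numeric"]], " numeric, ", tp[["nominal"]], " nominal\n", sep = "")
  }
  invisible(x)
}

#' Number of compounds in a dataset
#' @param dataset A `cs_dataset`.
#' @return Integer count.
#' @export
n_compounds <- function(dataset) nrow(dataset$compounds)

#' Feature names of a dataset
#' @param dataset A `cs_dataset`.
#' @param include_endpoints Keep endpoint columns in the result?
#' @return Character vector of column names.
#' @export
feature_names <- function(dataset, include_endpoints = FALSE) {
  nm <- names(dataset$features)
  if (!include_endpoints) nm <- setdiff(nm, dataset$endpoints)
  nm
}

#' Extract a numeric feature matrix
#'
#' @param dataset A `cs_dataset`.
#' @param columns Numeric feature columns to use; default all non-endpoint
#'   numeric columns.
#' @param na_action `"reject"` (default) errors on missing values; `"impute"`
#'   replaces them with the column median.
#' @return Numeric matrix (compounds x features).
#' @export
feature_matrix <- function(dataset, columns = NULL,
                           na_action = c("reject", "impute")) {
  na_action <- match.arg(na_action)
  if (is.null(columns)) {
    columns <- feature_names(dataset)
    columns <- columns[dataset$feature_types[columns] == "numeric"]
  }
  missing_cols <- setdiff(columns, names(dataset$features))
  if (length(missing_cols))
    stop("unknown feature column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad_type <- columns[dataset$feature_types[columns] != "numeric"]
  if (length(bad_type))
    stop("non-numeric feature column(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(dataset$features[columns])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    if (na_action == "reject")
      stop("missing values in feature column(s): ",
           paste(columns[colSums(is.na(m)) > 0], collapse = ", "),
           "; use na_action = 'impute' or clean the data", call. = FALSE)
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- stats::median(m[, j], na.rm = TRUE)
    }
  }
  rownames(m) <- dataset$compounds$index
  m
}

#' Load a compound dataset from SDF or CSV
#'
#' SDF property fields and CSV columns become feature columns; column types are
#' inferred (all-parseable-as-number becomes numeric) unless overridden. For
#' CSV, a SMILES column may be named (or detected case-insensitively as
#' `smiles`); structure-free feature tables are allowed.
#'
#' @param path File path.
#' @param format `"sdf"`, `"csv"`, or `"auto"` (by extension).
#' @param smiles_column CSV column holding SMILES; `NA` for feature-only mode.
#' @param types Optional named character vector of type overrides
#'   (`"numeric"`/`"nominal"`).
#' @param endpoints Column names to flag as endpoints.
#' @param validate_structures Parse every structure through RDKit and store
#'   canonical SMILES (default `TRUE`); unparseable records raise an error
#'   naming the record index.
#' @param name_column Optional CSV column holding compound names.
#' @return A [cs_dataset].
#' @export
load_dataset <- function(path, format = c("auto", "sdf", "csv"),
                         smiles_column = NULL, types = NULL,
                         endpoints = character(0),
                         validate_structures = TRUE, name_column = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sdf = "sdf", sd = "sdf", csv = "csv",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  if (format == "csv") {
    load_dataset_csv(path, smiles_column, types, endpoints,
                     validate_structures, name_column)
  } else {
    load_dataset_sdf(path, types, endpoints, validate_structures)
  }
}

load_dataset_csv <- function(path, smiles_column, types, endpoints,
                             validate_structures, name_column) {
  header <- utils::read.csv(path, nrows = 1, check.names = FALSE,
                            colClasses = "character")
  if (nrow(header) == 0 && ncol(header) == 0) stop("empty file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = c("NA", ""))
  if (nrow(raw) == 0) stop("empty file (no data rows): ", path, call. = FALSE)
  if (anyDuplicated(names(raw)))
    stop("duplicate column names in ", path, ": ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "),
         call. = FALSE)
  if (is.null(smiles_column)) {
    hit <- which(tolower(names(raw)) == "smiles")
    smiles_column <- if (length(hit)) names(raw)[hit[1]] else NA
  }
  smiles <- NULL
  if (!is.na(smiles_column)) {
    if (!smiles_column %in% names(raw))
      stop("SMILES column '", smiles_column, "' not found", call. = FALSE)
    smiles <- raw[[smiles_column]]
    raw[[smiles_column]] <- NULL
    if (validate_structures) {
      canon <- tryCatch(canonical_smiles(smiles),
                        error = function(e) stop("row ", sub(".*index\\(es\\): ", "", conditionMessage(e)),
                                                 ": unparseable structure", call. = FALSE))
      smiles <- canon
    }
  }
  cmp_names <- NULL
  if (!is.null(name_column) && name_column %in% names(raw)) {
    cmp_names <- raw[[name_column]]
    raw[[name_column]] <- NULL
  }
  cs_dataset(smiles = smiles, features = raw, feature_types = types,
             endpoints = endpoints, names = cmp_names)
}

# Minimal V2000 SD-File reader: molblock + "> <field>" property blocks per
# record, records separated by "$$$$". Structures are canonicalised by RDKit.
load_dataset_sdf <- function(path, types, endpoints, validate_structures) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop("empty file: ", path, call. = FALSE)
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0) stop("no SDF records (missing $$$$) in ", path, call. = FALSE)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  records <- Map(function(s, e) lines[s:(e - 1L)], starts, ends)

  molblocks <- character(length(records))
  props <- vector("list", length(records))
  mol_names <- character(length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    m_end <- which(grepl("^M\\s+END", rec))
    if (length(m_end) == 0)
      stop("record ", i, ": malformed molblock (no 'M  END')", call. = FALSE)
    molblocks[i] <- paste(rec[1:m_end[1]], collapse = "\n")
    mol_names[i] <- trimws(rec[1])
    props[[i]] <- parse_sdf_properties(rec[-(1:m_end[1])])
  }

  all_fields <- unique(unlist(lapply(props, names)))
  features <- as.data.frame(
    stats::setNames(lapply(all_fields, function(f) {
      vapply(props, function(p) p[[f]] %||% NA_character_, character(1))
    }), all_fields),
    check.names = FALSE, stringsAsFactors = FALSE, optional = TRUE
  )
  if (length(all_fields) == 0) features <- data.frame(row.names = seq_along(records))

  smiles <- rep(NA_character_, length(records))
  if (validate_structures) {
    resp <- chem_bridge("molblock_to_smiles", molblocks = as.list(molblocks))
    if (!all(resp$ok))
      stop("unparseable molecule record(s): ",
           paste(which(!resp$ok), collapse = ", "), call. = FALSE)
    smiles <- as.character(resp$smiles)
  }
  cs_dataset(smiles = smiles, features = features, feature_types = types,
             endpoints = endpoints,
             names = ifelse(nzchar(mol_names), mol_names, NA_character_))
}

parse_sdf_properties <- function(lines) {
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[i]
    if (grepl("^>\\s*", line)) {
      field <- sub("^>.*?<([^>]*)>.*$", "\\1", line)
      vals <- character(0)
      i <- i + 1L
      while (i <= length(lines) && nzchar(trimws(lines[i]))) {
        vals <- c(vals, lines[i])
        i <- i + 1L
      }
      out[[field]] <- if (length(vals)) paste(vals, collapse = "\n") else NA_character_
    }
    i <- i + 1L
  }
  out
}

#' Write a dataset to SDF or CSV
#'
#' Round-trip guarantee: `load_dataset(write_dataset(d))` reproduces compound
#' order and feature values (numeric values to printed precision, 15
#' significant digits).
#'
#' @param dataset A [cs_dataset].
#' @param path Output path.
#' @param format `"sdf"`, `"csv"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, format = c("auto", "sdf", "csv")) {
  stopifnot(inherits(dataset, "cs_dataset"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sdf = "sdf", sd = "sdf", csv = "csv",
                     stop("cannot infer format from extension of ", path, call. = FALSE))
  }
  fmt_num <- function(x) ifelse(is.na(x), NA, format(x, digits = 15, trim = TRUE,
                                                     scientific = FALSE))
  feats <- dataset$features
  for (col in names(feats)) {
    if (dataset$feature_types[[col]] == "numeric") feats[[col]] <- fmt_num(feats[[col]])
  }
  if (format == "csv") {
    cols <- list()
    if (any(!is.na(dataset$compounds$smiles))) cols$smiles <- dataset$compounds$smiles
    cols <- c(cols, as.list(feats))
    if (length(cols) == 0)
      stop("dataset has neither structures nor features; nothing to write", call. = FALSE)
    out <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE,
                         optional = TRUE)
    ok <- tryCatch({
      utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write to ", path, call. = FALSE)
  } else {
    if (any(is.na(dataset$compounds$smiles)))
      stop("SDF output requires a structure (SMILES) for every compound", call. = FALSE)
    resp <- chem_bridge("smiles_to_molblock",
                        smiles = as.list(dataset$compounds$smiles),
                        names = as.list(ifelse(is.na(dataset$compounds$name), "",
                                               dataset$compounds$name)))
    con <- tryCatch(file(path, "w"), error = function(e)
      stop("cannot write to ", path, call. = FALSE))
    on.exit(close(con), add = TRUE)
    for (i in seq_len(n_compounds(dataset))) {
      block <- sub("\n$", "", resp$molblocks[[i]])
      writeLines(block, con)
      for (col in names(feats)) {
        val <- feats[[col]][i]
        if (!is.na(val)) writeLines(c(paste0(">  <", col, ">"), as.character(val), ""), con)
      }
      writeLines("$$$$", con)
    }
  }
  invisible(path)
}

#' Content hash of a dataset
#'
#' MD5 over the canonical SMILES list plus the printed feature table; used to
#' detect dataset/configuration mismatches.
#'
#' @param dataset A [cs_dataset].
#' @return Character MD5 digest.
#' @export
dataset_hash <- function(dataset) {
  stopifnot(inherits(dataset, "cs_dataset"))
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  con <- file(tmp, "w")
  writeLines(dataset$compounds$smiles, con)
  writeLines(unlist(lapply(names(dataset$features), function(col) {
    c(col, dataset$feature_types[[col]],
      format(dataset$features[[col]], digits = 15, trim = TRUE))
  })), con)
  close(con)
  unname(tools::md5sum(tmp))
}
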