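#' @title RDKit bridge
#' @description
#' All structure-dependent computations (SMILES parsing, SMARTS substructure
#' matching, molecular descriptors, SDF molblock interconversion) are delegated
#' to the RDKit toolkit through a small Python helper shipped with the package.
#' Requests and responses are exchanged as JSON files; errors raised on the
#' Python side are rethrown as R conditions.
#' @keywords internal
#' @name chem-bridge
NULL

bridge_script <- function() {
  path <- system.file("python", "chem_bridge.py", package = "chemspacemap")
  if (!nzchar(path)) stop("bridge script not found; package installation is broken")
  path
}

#' Locate the python interpreter used for RDKit calls
#'
#' Honours the option `chemspacemap.python` (default `"python"` on PATH).
#' @return Path or command name of the interpreter.
#' @keywords internal
python_command <- function() {
  getOption("chemspacemap.python", "python")
}

#' Run a task on the RDKit bridge
#'
#' @param task Task name understood by `inst/python/chem_bridge.py`.
#' @param ... Task payload fields (vectors/lists serialisable to JSON).
#' @return The parsed JSON response (a list).
#' @keywords internal
chem_bridge <- function(task, ...) {
  req <- c(list(task = task), list(...))
  req_file <- tempfile(fileext = ".json")
  resp_file <- tempfile(fileext = ".json")
  on.exit(unlink(c(req_file, resp_file)), add = TRUE)
  jsonlite::write_json(req, req_file, auto_unbox = TRUE, digits = NA, null = "null")
  status <- suppressWarnings(system2(
    python_command(),
    args = c(shQuote(bridge_script()), shQuote(req_file), shQuote(resp_file)),
    stdout = FALSE, stderr = FALSE
  ))
  if (!identical(status, 0L) || !file.exists(resp_file)) {
    stop("RDKit bridge failed (python exit status ", status,
         "); is python with rdkit on PATH?")
  }
  resp <- jsonlite::read_json(resp_file, simplifyVector = TRUE)
  if (!is.null(resp$error)) stop("RDKit: ", resp$error, call. = FALSE)
  resp
}

#' Canonicalise SMILES strings via RDKit
#'
#' @param smiles Character vector of SMILES.
#' @param strict Error on unparseable entries (default) instead of returning NA.
#' @return Character vector of canonical SMILES (NA where unparseable and
#'   `strict = FALSE`).
#' @export
canonical_smiles <- function(smiles, strict = TRUE) {
  if (length(smiles) == 0) return(character(0))
  resp <- chem_bridge("parse_smiles", smiles = as.list(as.character(smiles)))
  ok <- resp$ok
  if (strict && !all(ok)) {
    stop("unparseable SMILES at record index(es): ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  out <- as.character(resp$canonical)
  out[!ok] <- NA_character_
  out
}
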