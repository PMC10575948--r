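# Bridge to the RDKit chemistry backend. All chemistry (canonical SMILES,
# Murcko scaffolds, descriptors, fingerprints) is computed by RDKit through
# one batched subprocess call; results for canonicalization/scaffolds are
# cached per session since they are pure functions of the SMILES string.

.chem_cache <- new.env(parent = emptyenv())

backend_python <- function() {
  py <- getOption("qsareval.python", Sys.getenv("QSAREVAL_PYTHON", ""))
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("No python interpreter found; set options(qsareval.python=)", call. = FALSE)
  py
}

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "qsareval")
  if (!nzchar(path)) stop("chem_backend.py not found in installed package", call. = FALSE)
  path
}

backend_call <- function(args) {
  res <- suppressWarnings(system2(backend_python(), c(shQuote(backend_script()), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("chemistry backend failed: ", paste(res, collapse = "\n"), call. = FALSE)
  }
  invisible(res)
}

#' Report the RDKit version used by the chemistry backend
#'
#' @return A single character string (the RDKit version).
#' @export
rdkit_version <- function() {
  if (is.null(.chem_cache$version)) {
    .chem_cache$version <- backend_call("version")[1]
  }
  .chem_cache$version
}

# Batched canonicalization + scaffold lookup with caching. Returns a
# data.frame(smiles, canonical, valid, scaffold) aligned with the input.
chem_canon <- function(smiles) {
  stopifnot(is.character(smiles))
  key <- paste0("s:", smiles)
  miss <- unique(smiles[!vapply(key, exists, logical(1), envir = .chem_cache)])
  if (length(miss)) {
    fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".csv")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    writeLines(miss, fin)
    backend_call(c("canon", shQuote(fin), shQuote(fout)))
    got <- utils::read.csv(fout, colClasses = c("character", "integer", "character"))
    stopifnot(nrow(got) == length(miss))
    for (i in seq_along(miss)) {
      assign(paste0("s:", miss[i]),
             list(canonical = got$canonical[i], valid = got$valid[i] == 1L,
                  scaffold = got$scaffold[i]),
             envir = .chem_cache)
    }
  }
  hits <- lapply(key, get, envir = .chem_cache)
  data.frame(
    smiles = smiles,
    canonical = vapply(hits, `[[`, character(1), "canonical"),
    valid = vapply(hits, `[[`, logical(1), "valid"),
    scaffold = vapply(hits, `[[`, character(1), "scaffold"),
    stringsAsFactors = FALSE
  )
}

# Raw feature matrix from the backend; failed rows come back as NA.
chem_features <- function(smiles, name, params = list()) {
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(smiles, fin)
  backend_call(c("feat", shQuote(fin), shQuote(fout), name,
                 shQuote(jsonlite::toJSON(params, auto_unbox = TRUE))))
  mat <- as.matrix(data.table::fread(fout, header = TRUE, na.strings = "NA"))
  stopifnot(nrow(mat) == length(smiles))
  mat
}
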