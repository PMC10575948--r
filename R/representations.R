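REPRESENTATIONS <- c("PhysChem", "RDKit2D", "MACCS", "MorganBits",
                     "MorganCounts", "AtomPairs")

PHYSCHEM_COLUMNS <- c("MolWt", "MolLogP", "NumHDonors", "NumHAcceptors",
                      "NumRotatableBonds", "NumAtoms", "NumHeavyAtoms",
                      "MolMR", "PSA", "FormalCharge", "NumRings")

#' Compute a fixed molecular representation
#'
#' Featurizes a set of molecules with one of the fixed representations used
#' throughout the benchmark: the 11 drug-likeness PhysChem descriptors, the
#' full RDKit 2D descriptor set (~200 columns, dimensionality recorded from
#' the toolkit at run time), 166-key MACCS structural keys, Morgan
#' (ECFP-style) bit or count fingerprints, or hashed atom-pair fingerprints.
#' Morgan fingerprints default to radius 2 and 2048 bits. Descriptor
#' failures for single molecules are imputed with the column median of the
#' successful rows and recorded in the `imputed` attribute.
#'
#' @param name One of PhysChem, RDKit2D, MACCS, MorganBits, MorganCounts,
#'   AtomPairs.
#' @param molecules Either a `curated_dataset` or a data.frame with columns
#'   `id` and `smiles` (valid canonical SMILES).
#' @param radius Morgan radius (default 2).
#' @param n_bits Fingerprint width for Morgan/AtomPairs (default 2048).
#' @param normalize For RDKit2D: rank-based normalization of each column to
#'   (0, 1) (default off).
#' @return A `feature_matrix`: numeric matrix with molecule ids as rownames
#'   and attributes `representation`, `params`, `column_kind` (bit/count/
#'   continuous), `imputed` (ids of imputed rows) and `toolkit_version`.
#' @export
compute_representation <- function(name, molecules, radius = 2, n_bits = 2048,
                                   normalize = FALSE) {
  if (!name %in% REPRESENTATIONS) {
    stop("unknown representation '", name, "'; choose one of: ",
         paste(REPRESENTATIONS, collapse = ", "))
  }
  if (inherits(molecules, "curated_dataset")) molecules <- molecules$data
  stopifnot(all(c("id", "smiles") %in% names(molecules)))
  params <- switch(name,
    MorganBits = , MorganCounts = list(radius = radius, n_bits = n_bits),
    AtomPairs = list(n_bits = n_bits),
    RDKit2D = list(normalize = normalize),
    list())
  mat <- chem_features(molecules$smiles, name, params)
  rownames(mat) <- molecules$id
  if (name == "PhysChem") colnames(mat) <- PHYSCHEM_COLUMNS

  imputed <- character(0)
  bad <- rowSums(is.na(mat)) > 0
  if (any(bad)) {
    imputed <- molecules$id[bad]
    med <- apply(mat[!bad, , drop = FALSE], 2, stats::median)
    med[is.na(med)] <- 0
    for (j in which(colSums(is.na(mat)) > 0)) {
      mat[is.na(mat[, j]), j] <- med[j]
    }
  }
  if (name == "RDKit2D" && normalize) {
    mat <- apply(mat, 2, function(v) rank(v, ties.method = "average") / (length(v) + 1))
    rownames(mat) <- molecules$id
  }
  kind <- switch(name,
    MorganBits = , AtomPairs = , MACCS = "bit",
    MorganCounts = "count",
    "continuous")
  structure(mat,
            representation = name, params = params, column_kind = kind,
            imputed = imputed, toolkit_version = rdkit_version(),
            class = c("feature_matrix", class(mat)))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix %s> %d molecules x %d columns (%s)\n",
              attr(x, "representation"), nrow(x), ncol(x), attr(x, "column_kind")))
  invisible(x)
}

#' Tanimoto similarity between two bit vectors
#'
#' |a AND b| / |a OR b|. Two all-zero vectors are defined as identical
#' (similarity 1).
#'
#' @param fp_a,fp_b Equal-length 0/1 vectors.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) stop("fingerprint length mismatch")
  a <- fp_a != 0; b <- fp_b != 0
  un <- sum(a | b)
  if (un == 0) return(1.0)
  sum(a & b) / un
}

# All-pairs Tanimoto between the rows of two bit matrices (queries x refs).
tanimoto_matrix <- function(query, ref) {
  if (ncol(query) != ncol(ref)) stop("fingerprint length mismatch")
  q <- (query != 0) * 1; r <- (ref != 0) * 1
  inter <- q %*% t(r)
  un <- outer(rowSums(q), rowSums(r), "+") - inter
  sim <- ifelse(un == 0, 1.0, inter / pmax(un, 1))
  sim
}

#' Persist a feature matrix as CSV with a JSON sidecar
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path; provenance goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(id = rownames(fm), as.data.frame(unclass(fm)),
                   check.names = FALSE)
  data.table::fwrite(df, path)
  jsonlite::write_json(
    list(representation = attr(fm, "representation"),
         params = attr(fm, "params"),
         column_kind = attr(fm, "column_kind"),
         toolkit_version = attr(fm, "toolkit_version")),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
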