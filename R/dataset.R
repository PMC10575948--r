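#' Canonicalize SMILES strings
#'
#' Converts raw SMILES to the RDKit canonical form. Invalid strings never
#' raise an error; they are flagged so the caller can decide.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A data.frame with columns `smiles` (input), `canonical` (empty for
#'   invalid input), `valid` (logical) and `scaffold` (canonical Bemis-Murcko
#'   scaffold, empty for acyclic or invalid molecules).
#' @examples \dontrun{canonicalize("OCC")}
#' @export
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles), !anyNA(smiles), all(nzchar(smiles)))
  chem_canon(smiles)
}

#' Bemis-Murcko scaffold of a valid canonical SMILES
#'
#' The scaffold keeps ring systems and linkers and strips side chains;
#' acyclic molecules map to the empty string. Invalid input is a contract
#' violation and raises an error (unlike [canonicalize()]).
#'
#' @param smiles Character vector of valid SMILES.
#' @return Character vector of canonical scaffold SMILES ("" for acyclic).
#' @export
murcko_scaffold <- function(smiles) {
  res <- chem_canon(smiles)
  if (any(!res$valid)) {
    stop("invalid SMILES passed to murcko_scaffold: ",
         paste(utils::head(smiles[!res$valid], 5), collapse = ", "))
  }
  res$scaffold
}

#' Convert a potency in nM to pIC50
#'
#' pIC50 = 9 - log10(value in nM), i.e. the negative decadic logarithm of the
#' molar concentration (1000 nM = 1 uM gives pIC50 6).
#'
#' @param value_nM Positive numeric vector of potencies in nM.
#' @return Numeric vector of pIC50 values.
#' @export
to_pic50 <- function(value_nM) {
  if (!is.numeric(value_nM) || any(!is.finite(value_nM)) || any(value_nM <= 0)) {
    stop("value_nM must be positive and finite")
  }
  9 - log10(value_nM)
}

#' Read an activity or benchmark CSV
#'
#' Accepts two dialects: activity tables with columns `smiles`, `value`
#' (in nM) and optional `target`, `measure`, `relation`; or benchmark tables
#' with `smiles`, `label`. Rows with a relation other than "=" are rejected
#' at load time. For activity tables the pIC50 label is derived via
#' [to_pic50()]; `measure` may be restricted to one of IC50/EC50/Ki/Kd.
#'
#' @param path CSV file with a header.
#' @param measure Optional single measure type to retain (default: pool all).
#' @return A data.frame with columns `smiles` and `label` (plus the original
#'   columns), ready for [curate()].
#' @export
read_activity_csv <- function(path, measure = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!"smiles" %in% names(tab)) stop("CSV must have a 'smiles' column")
  if ("relation" %in% names(tab)) {
    bad <- tab$relation != "="
    if (any(bad)) {
      warning(sum(bad), " rows with relation != '=' rejected")
      tab <- tab[!bad, , drop = FALSE]
    }
  }
  if (!is.null(measure)) {
    stopifnot(measure %in% c("IC50", "EC50", "Ki", "Kd"))
    if (!"measure" %in% names(tab)) stop("no 'measure' column to filter on")
    tab <- tab[tab$measure == measure, , drop = FALSE]
  }
  if ("label" %in% names(tab)) {
    tab$label <- as.numeric(tab$label)
  } else if ("value" %in% names(tab)) {
    tab$label <- to_pic50(as.numeric(tab$value))
  } else {
    stop("CSV must have a 'label' or 'value' column")
  }
  tab
}

new_curated_dataset <- function(name, task, data, cutoff = NULL, curation_log = list()) {
  stopifnot(task %in% c("regression", "classification"))
  structure(list(name = name, task = task, data = data, cutoff = cutoff,
                 curation_log = curation_log),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat(sprintf("<curated_dataset '%s'> %d molecules, task = %s\n",
              x$name, nrow(x$data), x$task))
  if (!is.null(x$cutoff)) cat("  cutoff:", x$cutoff, "\n")
  if (length(x$curation_log)) {
    cat("  curation:", paste(names(x$curation_log), unlist(x$curation_log),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of molecules in a curated dataset
#' @param x A `curated_dataset`.
#' @return Integer count.
#' @export
n_molecules <- function(x) nrow(x$data)

#' Curate raw activity rows into a deduplicated pIC50 dataset
#'
#' Canonicalizes SMILES, drops unparsable and over-length molecules,
#' collapses exact duplicates (same canonical SMILES and identical pIC50),
#' aggregates repeated measurements by their median when the value span is
#' at most `contradiction_span` pIC50 units, and drops the molecule as
#' contradictory when the span exceeds it. The result holds one record per
#' canonical SMILES with its Bemis-Murcko scaffold, and is independent of
#' input row order.
#'
#' @param records data.frame with columns `smiles` and `label` (pIC50), as
#'   returned by [read_activity_csv()].
#' @param name Dataset name.
#' @param max_len Maximum raw SMILES length in characters (default 400).
#' @param contradiction_span Maximum tolerated pIC50 span among repeated
#'   measurements of one molecule (default 1.0 log unit, roughly assay
#'   reproducibility).
#' @return A `curated_dataset` (regression task) whose `data` has columns
#'   id, smiles_raw, smiles, smiles_length, scaffold, label; `curation_log`
#'   counts invalid, over-length, duplicate and contradictory removals.
#' @export
curate <- function(records, name = "dataset", max_len = 400,
                   contradiction_span = 1.0) {
  stopifnot(is.data.frame(records), all(c("smiles", "label") %in% names(records)))
  log <- list(invalid_removed = 0L, overlength_removed = 0L,
              duplicates_removed = 0L, contradictory_removed = 0L)

  raw_len <- nchar(records$smiles)
  over <- raw_len > max_len
  log$overlength_removed <- sum(over)
  records <- records[!over, , drop = FALSE]

  can <- canonicalize(records$smiles)
  log$invalid_removed <- sum(!can$valid)
  keep <- can$valid
  tab <- data.frame(smiles_raw = records$smiles[keep],
                    smiles = can$canonical[keep],
                    scaffold = can$scaffold[keep],
                    label = records$label[keep],
                    stringsAsFactors = FALSE)
  # order-independence: sort before any aggregation
  tab <- tab[order(tab$smiles, tab$label, tab$smiles_raw), , drop = FALSE]

  exact_dupe <- duplicated(tab[c("smiles", "label")])
  log$duplicates_removed <- sum(exact_dupe)
  tab <- tab[!exact_dupe, , drop = FALSE]

  spans <- tapply(tab$label, tab$smiles, function(v) max(v) - min(v))
  contra <- names(spans)[spans > contradiction_span]
  log$contradictory_removed <- length(contra)
  tab <- tab[!tab$smiles %in% contra, , drop = FALSE]

  agg <- do.call(rbind, lapply(split(tab, tab$smiles), function(g) {
    data.frame(smiles_raw = g$smiles_raw[1], smiles = g$smiles[1],
               scaffold = g$scaffold[1], label = stats::median(g$label),
               stringsAsFactors = FALSE)
  }))
  if (is.null(agg) || nrow(agg) == 0) stop("curation removed every molecule")
  agg <- agg[order(agg$smiles), , drop = FALSE]
  rownames(agg) <- NULL
  data <- data.frame(id = sprintf("M%05d", seq_len(nrow(agg))),
                     smiles_raw = agg$smiles_raw, smiles = agg$smiles,
                     smiles_length = nchar(agg$smiles_raw),
                     scaffold = agg$scaffold, label = agg$label,
                     stringsAsFactors = FALSE)
  new_curated_dataset(name, "regression", data, curation_log = log)
}

#' Binarize a regression dataset at a pIC50 cutoff
#'
#' Molecules with pIC50 greater than or equal to the cutoff become active
#' (1), the rest inactive (0); "pIC50 less than 6 inactive otherwise active".
#'
#' @param dataset A regression `curated_dataset`.
#' @param cutoff Activity cutoff in pIC50 units (default 6, i.e. 1 uM).
#' @return A classification `curated_dataset` with labels in \{0, 1\} and the
#'   cutoff recorded.
#' @export
binarize <- function(dataset, cutoff = 6.0) {
  stopifnot(inherits(dataset, "curated_dataset"))
  if (dataset$task != "regression") stop("binarize expects a regression dataset")
  out <- dataset
  out$task <- "classification"
  out$cutoff <- cutoff
  out$data$pic50 <- dataset$data$label
  out$data$label <- as.integer(dataset$data$label >= cutoff)
  out
}

#' Write a curated dataset to CSV (+ JSON curation log)
#'
#' @param dataset A `curated_dataset`.
#' @param path Output CSV path; the curation log goes to `<path>.log.json`.
#' @return `path`, invisibly.
#' @export
write_curated_csv <- function(dataset, path) {
  utils::write.csv(dataset$data[, c("id", "smiles", "scaffold", "label")],
                   path, row.names = FALSE)
  jsonlite::write_json(dataset$curation_log, paste0(path, ".log.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
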