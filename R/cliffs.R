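#' Annotate activity-cliff scaffolds and molecules
#'
#' A scaffold is an AC (activity-cliff) scaffold when the pIC50 values of
#' its members span at least `span_threshold` log units ("at least two
#' orders of magnitude within one scaffold"); every molecule bearing an AC
#' scaffold is an AC molecule. Singleton scaffolds have span 0 and are never
#' AC. Computed on the full curated dataset; per-split AC fractions are
#' derived afterwards from manifests.
#'
#' @param dataset A regression `curated_dataset` with scaffolds.
#' @param span_threshold Inclusive span threshold in pIC50 units (default 2).
#' @return An `ac_annotation`: `scaffolds` (scaffold, size, span, is_ac),
#'   `molecules` (id, scaffold, is_ac), and `summary` with counts and
#'   percentages of AC scaffolds and AC molecules (Table-1 shape).
#' @export
annotate_cliffs <- function(dataset, span_threshold = 2.0) {
  stopifnot(inherits(dataset, "curated_dataset"))
  if (dataset$task != "regression") {
    stop("annotate_cliffs needs regression labels (span undefined for binary)")
  }
  data <- dataset$data
  grp <- split(data$label, data$scaffold)
  scaffolds <- data.frame(
    scaffold = names(grp),
    size = lengths(grp),
    span = vapply(grp, function(v) max(v) - min(v), numeric(1)),
    stringsAsFactors = FALSE
  )
  scaffolds$is_ac <- scaffolds$span >= span_threshold & scaffolds$size >= 2
  rownames(scaffolds) <- NULL
  mol <- data.frame(id = data$id, scaffold = data$scaffold,
                    stringsAsFactors = FALSE)
  mol$is_ac <- scaffolds$is_ac[match(mol$scaffold, scaffolds$scaffold)]
  summary <- list(
    n_scaffolds = nrow(scaffolds),
    n_molecules = nrow(mol),
    ac_scaffolds = sum(scaffolds$is_ac),
    ac_scaffold_pct = 100 * sum(scaffolds$is_ac) / nrow(scaffolds),
    ac_molecules = sum(mol$is_ac),
    ac_molecule_pct = 100 * sum(mol$is_ac) / nrow(mol),
    span_threshold = span_threshold
  )
  structure(list(scaffolds = scaffolds, molecules = mol, summary = summary),
            class = "ac_annotation")
}

#' @export
print.ac_annotation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ac_annotation> %d scaffolds, %d molecules; AC scaffolds %d (%.1f%%), AC molecules %d (%.1f%%)\n",
              s$n_scaffolds, s$n_molecules, s$ac_scaffolds, s$ac_scaffold_pct,
              s$ac_molecules, s$ac_molecule_pct))
  invisible(x)
}

#' Flag near-cutoff edge-case molecules
#'
#' A scaffold group is an edge group when it holds at least one member with
#' pIC50 in \[window\[1\], cutoff) and one in \[cutoff, window\[2\]\] — analogs
#' straddling the activity cutoff inside the fragile 5-7 window, whose
#' binarized labels are coerced into opposite classes. Within edge groups,
#' members with pIC50 inside the window are flagged as edge cases.
#'
#' @param dataset A regression `curated_dataset`.
#' @param window Two-sided pIC50 window (default c(5, 7)).
#' @param cutoff Activity cutoff, must lie inside the window (default 6).
#' @return data.frame(id, scaffold, is_edge).
#' @export
find_edge_cases <- function(dataset, window = c(5, 7), cutoff = 6.0) {
  stopifnot(inherits(dataset, "curated_dataset"))
  if (dataset$task != "regression") stop("find_edge_cases needs regression labels")
  if (!(cutoff > window[1] && cutoff < window[2])) {
    stop("cutoff must lie strictly inside the window")
  }
  data <- dataset$data
  grp <- split(seq_len(nrow(data)), data$scaffold)
  is_edge <- logical(nrow(data))
  for (idx in grp) {
    v <- data$label[idx]
    lo <- v >= window[1] & v < cutoff
    hi <- v >= cutoff & v <= window[2]
    if (any(lo) && any(hi)) {
      is_edge[idx[v >= window[1] & v <= window[2]]] <- TRUE
    }
  }
  data.frame(id = data$id, scaffold = data$scaffold, is_edge = is_edge,
             stringsAsFactors = FALSE)
}

#' Stratify a prediction set by activity-cliff and edge status
#'
#' @param pred A `prediction_set` (see [train_and_predict()]).
#' @param ann An `ac_annotation` covering all predicted ids.
#' @param edge Optional edge-case flags from [find_edge_cases()]; required
#'   for the `edge_removed` view.
#' @return Named list of `prediction_set` views: `all`, `ac`, `non_ac`, and
#'   (when `edge` is given) `edge_removed`; each tagged via the `subset`
#'   attribute.
#' @export
stratify_predictions <- function(pred, ann, edge = NULL) {
  stopifnot(inherits(pred, "prediction_set"), inherits(ann, "ac_annotation"))
  unknown <- setdiff(pred$id, ann$molecules$id)
  if (length(unknown)) {
    stop("prediction ids missing from annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  is_ac <- ann$molecules$is_ac[match(pred$id, ann$molecules$id)]
  views <- list(
    all = pred,
    ac = pred[is_ac, , drop = FALSE],
    non_ac = pred[!is_ac, , drop = FALSE]
  )
  if (!is.null(edge)) {
    is_edge <- edge$is_edge[match(pred$id, edge$id)]
    views$edge_removed <- pred[!is_edge, , drop = FALSE]
  }
  for (nm in names(views)) {
    views[[nm]] <- restore_prediction_set(views[[nm]], pred, subset = nm)
  }
  views
}

#' Correlation between per-split error and activity-cliff burden
#'
#' Pearson correlation between per-split RMSE values and the corresponding
#' fraction of AC molecules (per partition), echoing the diagnostic that
#' error grows with the planted cliff burden.
#'
#' @param per_split_rmse,per_split_ac_fraction Equal-length numeric vectors
#'   (one entry per split), length >= 3.
#' @return Pearson correlation, or `NA` when either vector has zero variance.
#' @export
ac_burden_correlation <- function(per_split_rmse, per_split_ac_fraction) {
  if (length(per_split_rmse) != length(per_split_ac_fraction)) {
    stop("length mismatch")
  }
  if (length(per_split_rmse) < 3) stop("need at least 3 splits")
  if (stats::sd(per_split_rmse) == 0 || stats::sd(per_split_ac_fraction) == 0) {
    return(NA_real_)
  }
  stats::cor(per_split_rmse, per_split_ac_fraction)
}

#' Fraction of AC molecules in each partition of a manifest
#'
#' @param manifest A `split_manifest`.
#' @param ann An `ac_annotation`.
#' @return Named numeric vector (train, val, test) of AC fractions.
#' @export
ac_fraction <- function(manifest, ann) {
  flag <- ann$molecules$is_ac
  names(flag) <- ann$molecules$id
  vapply(list(train = manifest$train_ids, val = manifest$val_ids,
              test = manifest$test_ids),
         function(ids) mean(flag[ids]), numeric(1))
}

#' Persist an AC annotation (scaffold CSV, molecule CSV, summary JSON)
#'
#' @param ann An `ac_annotation`.
#' @param prefix Path prefix; writes `<prefix>_scaffolds.csv`,
#'   `<prefix>_molecules.csv`, `<prefix>_summary.json`.
#' @return `prefix`, invisibly.
#' @export
write_annotation <- function(ann, prefix) {
  utils::write.csv(ann$scaffolds, paste0(prefix, "_scaffolds.csv"), row.names = FALSE)
  utils::write.csv(ann$molecules, paste0(prefix, "_molecules.csv"), row.names = FALSE)
  jsonlite::write_json(ann$summary, paste0(prefix, "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
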