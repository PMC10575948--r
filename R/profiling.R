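#' Kolmogorov D statistic between two samples
#'
#' The supremum over all points of the absolute difference between the two
#' empirical cumulative distribution functions — the two-sample KS statistic
#' without any p-value attached. Used to quantify label-distribution
#' divergence between dataset partitions.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return D in \[0, 1\].
#' @export
kolmogorov_d <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("samples must be non-empty")
  stopifnot(is.numeric(sample_a), is.numeric(sample_b))
  pts <- sort(unique(c(sample_a, sample_b)))
  fa <- stats::ecdf(sample_a); fb <- stats::ecdf(sample_b)
  max(abs(fa(pts) - fb(pts)))
}

#' Nearest-neighbor Tanimoto similarity of query molecules to a reference set
#'
#' For each query molecule, the maximum Tanimoto similarity to any reference
#' molecule — the standard train/test structural-similarity diagnostic.
#'
#' @param features_ref,features_query Bit-valued `feature_matrix` objects of
#'   the same representation and parameters.
#' @return List with `values` (one max-similarity per query row, named by
#'   molecule id) and `summary` (quartiles, median, mean).
#' @export
cross_set_similarity <- function(features_ref, features_query) {
  for (a in c("representation", "params")) {
    if (!identical(attr(features_ref, a), attr(features_query, a))) {
      stop("reference and query feature matrices differ in ", a)
    }
  }
  if (!identical(attr(features_ref, "column_kind"), "bit")) {
    stop("cross_set_similarity requires bit-valued fingerprints")
  }
  sim <- tanimoto_matrix(unclass(features_query), unclass(features_ref))
  values <- apply(sim, 1, max)
  names(values) <- rownames(features_query)
  list(values = values,
       summary = c(stats::quantile(values, c(0.25, 0.5, 0.75)),
                   mean = mean(values)))
}

#' Per-descriptor Pearson correlation with the label
#'
#' @param dataset A regression `curated_dataset`.
#' @param features A `feature_matrix` (typically PhysChem) whose rownames
#'   cover the dataset ids.
#' @return Named numeric vector of Pearson correlations, `NA` for
#'   zero-variance descriptor columns (undefined, never silently 0).
#' @export
descriptor_label_correlation <- function(dataset, features) {
  stopifnot(inherits(dataset, "curated_dataset"))
  if (dataset$task != "regression") stop("needs regression labels")
  if (n_molecules(dataset) < 3) stop("need at least 3 molecules")
  mat <- unclass(features)[dataset$data$id, , drop = FALSE]
  y <- dataset$data$label
  apply(mat, 2, function(v) {
    if (stats::sd(v) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(v, y)
  })
}

# Adjusted Fisher-Pearson skewness coefficient.
skewness_coef <- function(x) {
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0) return(NA_real_)
  m3 <- mean((x - mean(x))^3)
  g1 <- m3 / (stats::sd(x) * sqrt((n - 1) / n))^3
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Profile the label and structure divergence of one split
#'
#' Summarizes per-partition labels (mean, skew, positive rate for
#' classification), pairwise Kolmogorov D between partition label
#' distributions, and (optionally) nearest-neighbor Tanimoto similarity of
#' validation/test molecules to the training set.
#'
#' @param dataset A `curated_dataset`.
#' @param manifest A `split_manifest` for it.
#' @param features Optional bit `feature_matrix` for the similarity block.
#' @return A `profile_report` list with elements `labels`, `kolmogorov_d`
#'   and `similarity`.
#' @export
profile_split <- function(dataset, manifest, features = NULL) {
  parts <- list(train = manifest$train_ids, val = manifest$val_ids,
                test = manifest$test_ids)
  lab <- dataset$data$label
  names(lab) <- dataset$data$id
  labels <- lapply(parts, function(ids) {
    v <- lab[ids]
    s <- list(n = length(v), mean = mean(v), sd = stats::sd(v),
              skew = skewness_coef(v))
    if (dataset$task == "classification") s$positive_rate <- mean(v == 1)
    s
  })
  pairs <- list(c("train", "val"), c("train", "test"), c("val", "test"))
  d <- vapply(pairs, function(p) kolmogorov_d(lab[parts[[p[1]]]], lab[parts[[p[2]]]]),
              numeric(1))
  names(d) <- vapply(pairs, paste, character(1), collapse = "_")
  sim <- NULL
  if (!is.null(features)) {
    fm <- unclass(features)
    sim <- lapply(parts[c("val", "test")], function(ids) {
      cross_set_similarity(
        structure(fm[parts$train, , drop = FALSE],
                  representation = attr(features, "representation"),
                  params = attr(features, "params"),
                  column_kind = attr(features, "column_kind")),
        structure(fm[ids, , drop = FALSE],
                  representation = attr(features, "representation"),
                  params = attr(features, "params"),
                  column_kind = attr(features, "column_kind")))$summary
    })
  }
  structure(list(labels = labels, kolmogorov_d = d, similarity = sim),
            class = "profile_report")
}
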