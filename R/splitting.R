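new_split_manifest <- function(dataset_name, method, seed, ratios,
                               train_ids, val_ids, test_ids) {
  structure(list(dataset = dataset_name, method = method, seed = seed,
                 ratios = ratios, train_ids = train_ids, val_ids = val_ids,
                 test_ids = test_ids),
            class = "split_manifest")
}

#' @export
print.split_manifest <- function(x, ...) {
  cat(sprintf("<split_manifest %s/%s seed=%d> train=%d val=%d test=%d\n",
              x$dataset, x$method, x$seed, length(x$train_ids),
              length(x$val_ids), length(x$test_ids)))
  invisible(x)
}

check_ratios <- function(ratios) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
}

#' Random train/validation/test split
#'
#' Seeded permutation of the molecule ids; train takes the first
#' floor(r_train * n), validation the next floor(r_val * n), test the rest.
#'
#' @param dataset A `curated_dataset`.
#' @param ratios Train/val/test fractions summing to 1 (default 80:10:10).
#' @param seed Integer seed; the only source of randomness.
#' @return A `split_manifest`.
#' @export
random_split <- function(dataset, ratios = c(0.8, 0.1, 0.1), seed = 0) {
  check_ratios(ratios)
  ids <- dataset$data$id
  n <- length(ids)
  n_train <- floor(ratios[1] * n); n_val <- floor(ratios[2] * n)
  if (n_train < 1 || n_val < 1 || n - n_train - n_val < 1) {
    stop("dataset too small to populate all three partitions")
  }
  perm <- withr::with_seed(seed, sample.int(n))
  ids <- ids[perm]
  new_split_manifest(dataset$name, "random", seed, ratios,
                     ids[seq_len(n_train)],
                     ids[n_train + seq_len(n_val)],
                     ids[(n_train + n_val + 1):n])
}

#' Balanced Bemis-Murcko scaffold split
#'
#' Groups molecules by scaffold (acyclic molecules form the single
#' empty-scaffold group) and assigns whole groups to partitions so no
#' scaffold crosses a partition boundary. Groups larger than half the test
#' target are queued first (largest first, ties by scaffold string); the
#' remaining groups are shuffled with the seed. Groups fill train until its
#' target is met, then validation, then test.
#'
#' @inheritParams random_split
#' @return A `split_manifest` with zero cross-partition scaffold overlap.
#' @export
scaffold_split <- function(dataset, ratios = c(0.8, 0.1, 0.1), seed = 0) {
  check_ratios(ratios)
  data <- dataset$data
  groups <- split(data$id, data$scaffold)
  if (length(groups) < 3) stop("need at least 3 scaffold groups")
  n <- nrow(data)
  n_train <- floor(ratios[1] * n); n_val <- floor(ratios[2] * n)
  n_test <- n - n_train - n_val
  sizes <- lengths(groups)

  big <- sizes > n_test / 2
  big_order <- order(-sizes[big], names(groups)[big])
  small_names <- sort(names(groups)[!big])
  small_order <- withr::with_seed(seed, sample.int(length(small_names)))
  ordered <- c(groups[big][big_order], groups[small_names][small_order])

  train <- character(0); val <- character(0); test <- character(0)
  for (g in ordered) {
    if (length(train) < n_train) {
      train <- c(train, g)
    } else if (length(val) < n_val) {
      val <- c(val, g)
    } else {
      test <- c(test, g)
    }
  }
  if (length(val) == 0) stop("scaffold split could not populate the validation partition")
  if (length(test) == 0) stop("scaffold split could not populate the test partition")
  new_split_manifest(dataset$name, "scaffold", seed, ratios, train, val, test)
}

#' Run the multi-seed split protocol
#'
#' Produces one manifest per (method, seed) with seeds 0..n_seeds-1, the
#' protocol used for every downstream experiment (30 seeds by default).
#'
#' @inheritParams random_split
#' @param methods Subset of c("scaffold", "random").
#' @param n_seeds Number of seeds (default 30).
#' @param out_dir Optional directory; manifests are persisted there as JSON.
#' @return List of `split_manifest` objects, one per method x seed.
#' @export
split_protocol <- function(dataset, methods = c("scaffold", "random"),
                           n_seeds = 30, ratios = c(0.8, 0.1, 0.1),
                           out_dir = NULL) {
  stopifnot(all(methods %in% c("scaffold", "random")), n_seeds >= 1)
  manifests <- list()
  for (method in methods) {
    fun <- if (method == "scaffold") scaffold_split else random_split
    for (seed in 0:(n_seeds - 1)) {
      m <- tryCatch(fun(dataset, ratios, seed),
                    error = function(e) stop("split failed (method=", method,
                                             ", seed=", seed, "): ",
                                             conditionMessage(e), call. = FALSE))
      manifests[[paste(method, seed, sep = "_")]] <- m
      if (!is.null(out_dir)) {
        write_manifest(m, file.path(out_dir, sprintf("manifest_%s_%s_%02d.json",
                                                     dataset$name, method, seed)))
      }
    }
  }
  manifests
}

#' Write a split manifest to JSON
#' @param manifest A `split_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a split manifest from JSON
#' @param path JSON file written by [write_manifest()].
#' @return A `split_manifest`.
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_split_manifest(x$dataset, x$method, x$seed, x$ratios,
                     x$train_ids, x$val_ids, x$test_ids)
}
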