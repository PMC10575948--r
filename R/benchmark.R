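#' Configure a benchmark run
#'
#' @param dataset A `curated_dataset` (regression labels; classification
#'   cells binarize at `cutoff`).
#' @param representations Character vector of representation names.
#' @param models Character vector of model names ("RF", "SVM", "XGBoost").
#' @param methods Split methods, subset of c("scaffold", "random").
#' @param n_seeds Number of split seeds (default 30).
#' @param task "regression" or "classification".
#' @param cutoff Cutoff for classification cells (default 6).
#' @param out_dir Artifact directory (manifests, predictions, metrics).
#' @return A `benchmark_config`.
#' @export
benchmark_config <- function(dataset, representations = c("MorganBits"),
                             models = c("RF"), methods = c("scaffold", "random"),
                             n_seeds = 30, task = "regression", cutoff = 6.0,
                             out_dir = tempfile("qsareval_run_")) {
  stopifnot(inherits(dataset, "curated_dataset"),
            all(representations %in% REPRESENTATIONS),
            all(models %in% c("RF", "SVM", "XGBoost")),
            all(methods %in% c("scaffold", "random")))
  structure(list(dataset = dataset, representations = representations,
                 models = models, methods = methods, n_seeds = n_seeds,
                 task = match.arg(task, c("regression", "classification")),
                 cutoff = cutoff, out_dir = out_dir),
            class = "benchmark_config")
}

cell_key <- function(dataset_name, model, representation, method, seed, task) {
  rlang::hash(list(dataset_name, model, representation, method, seed, task))
}

#' Run the full benchmark grid
#'
#' curate/splits -> featurize -> train/predict -> metrics, over every
#' (representation, model, method, seed) cell. Every intermediate artifact
#' is persisted under `config$out_dir`; a rerun skips cells whose prediction
#' artifact already exists (content-addressed by provenance hash), and
#' failed cells are recorded without stopping independent cells.
#'
#' @param config A `benchmark_config`.
#' @param annotation Optional `ac_annotation` to add AC-stratified metric
#'   rows.
#' @return List with `metrics` (long data.frame), `failures` (data.frame of
#'   failed cells) and `out_dir`.
#' @export
run_benchmark <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "benchmark_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- config$dataset
  if (config$task == "classification" && dataset$task == "regression") {
    dataset <- binarize(dataset, config$cutoff)
  }
  manifests <- split_protocol(config$dataset, config$methods, config$n_seeds,
                              out_dir = file.path(config$out_dir, "manifests"))
  features <- lapply(stats::setNames(nm = config$representations),
                     function(r) compute_representation(r, dataset))
  metrics <- list(); failures <- list()
  for (rep_name in config$representations) {
    for (model in config$models) {
      for (m in manifests) {
        key <- cell_key(dataset$name, model, rep_name, m$method, m$seed,
                        config$task)
        pred_path <- file.path(config$out_dir, "predictions",
                               paste0(key, ".csv"))
        cell <- tryCatch({
          if (file.exists(pred_path)) {
            df <- utils::read.csv(pred_path, stringsAsFactors = FALSE)
            pred <- new_prediction_set(df, dataset$name, model, rep_name,
                                       m$method, m$seed, config$task)
          } else {
            spec <- model_spec(model, config$task, seed = m$seed)
            pred <- train_and_predict(spec, features[[rep_name]], dataset, m)
            write_predictions(pred, pred_path)
          }
          rows <- evaluate_predictions(pred)
          if (!is.null(annotation)) {
            views <- stratify_predictions(pred, annotation)
            for (v in c("ac", "non_ac")) {
              if (nrow(views[[v]]) >= 2 &&
                  (config$task != "classification" ||
                   length(unique(views[[v]]$y_true)) == 2)) {
                rows <- rbind(rows, evaluate_predictions(views[[v]]))
              }
            }
          }
          rows
        }, error = function(e) e)
        if (inherits(cell, "error")) {
          failures[[key]] <- data.frame(model = model, representation = rep_name,
                                        method = m$method, seed = m$seed,
                                        error = conditionMessage(cell),
                                        stringsAsFactors = FALSE)
        } else {
          metrics[[key]] <- cell
        }
      }
    }
  }
  metrics <- if (length(metrics)) do.call(rbind, c(metrics, make.row.names = FALSE)) else NULL
  failures <- if (length(failures)) do.call(rbind, c(failures, make.row.names = FALSE)) else NULL
  if (!is.null(metrics)) {
    utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  grid <- expand.grid(representation = config$representations,
                      model = config$models, method = config$methods,
                      seed = 0:(config$n_seeds - 1),
                      stringsAsFactors = FALSE)
  jsonlite::write_json(list(dataset = dataset$name, task = config$task,
                            n_cells = nrow(grid)),
                       file.path(config$out_dir, "grid.json"),
                       auto_unbox = TRUE)
  list(metrics = metrics, failures = failures, out_dir = config$out_dir)
}

#' Sweep classification cutoffs
#'
#' Re-binarizes a regression dataset at each cutoff, trains, and evaluates,
#' collecting per-cutoff metrics, the positive rate, and the predicted
#' probabilities of flagged edge-case molecules in the test set. Cutoffs
#' whose training partition is single-class are recorded as skipped, not
#' errors.
#'
#' @param dataset A regression `curated_dataset`.
#' @param cutoffs Numeric vector of pIC50 cutoffs.
#' @param spec_name Model name (default "RF").
#' @param representation Representation name (default "MorganBits").
#' @param manifests List of `split_manifest` objects to evaluate on.
#' @param edge Optional edge flags from [find_edge_cases()].
#' @return List with `metrics` (long data.frame with a cutoff column),
#'   `positive_rate` (per cutoff), `edge_scores` (per cutoff, predicted
#'   scores of edge molecules) and `skipped`.
#' @export
sweep_cutoffs <- function(dataset, cutoffs, spec_name = "RF",
                          representation = "MorganBits", manifests,
                          edge = NULL) {
  stopifnot(dataset$task == "regression")
  features <- compute_representation(representation, dataset)
  metrics <- list(); edge_scores <- list(); skipped <- character(0)
  pos_rate <- vapply(cutoffs, function(ct) mean(dataset$data$label >= ct),
                     numeric(1))
  names(pos_rate) <- as.character(cutoffs)
  for (ct in cutoffs) {
    bin <- binarize(dataset, ct)
    for (m in manifests) {
      key <- paste0("c", ct, "_", m$method, "_", m$seed)
      out <- tryCatch({
        spec <- model_spec(spec_name, "classification", seed = m$seed)
        pred <- train_and_predict(spec, features, bin, m)
        rows <- evaluate_predictions(pred)
        rows$cutoff <- ct
        if (!is.null(edge)) {
          flagged <- pred$id %in% edge$id[edge$is_edge]
          edge_scores[[key]] <- data.frame(cutoff = ct, seed = m$seed,
                                            id = pred$id[flagged],
                                            score = pred$score[flagged],
                                            stringsAsFactors = FALSE)
        }
        rows
      }, error = function(e) e)
      if (inherits(out, "error")) skipped <- c(skipped, key)
      else metrics[[key]] <- out
    }
  }
  list(metrics = if (length(metrics)) do.call(rbind, c(metrics, make.row.names = FALSE)) else NULL,
       positive_rate = pos_rate,
       edge_scores = if (length(edge_scores)) do.call(rbind, c(edge_scores, make.row.names = FALSE)) else NULL,
       skipped = skipped)
}
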