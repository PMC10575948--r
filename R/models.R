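#' Define a model specification
#'
#' Pinned baselines: RF (random forest, 500 trees), SVM (linear kernel),
#' XGBoost (gradient-boosted trees with library defaults), or `external`
#' (predictions supplied from outside, e.g. a deep model, so the statistics
#' layer can compare them without training here).
#'
#' @param name One of "RF", "SVM", "XGBoost", "external".
#' @param task "regression" or "classification".
#' @param seed Integer seed recorded in provenance and used for training.
#' @param hyperparameters Named list overriding the defaults (RF:
#'   `num_trees = 500`; XGBoost: `nrounds = 100`, `eta = 0.3`,
#'   `max_depth = 6`; SVM: `cost = 1`).
#' @return A `model_spec`.
#' @export
model_spec <- function(name = c("RF", "SVM", "XGBoost", "external"),
                       task = c("regression", "classification"),
                       seed = 0, hyperparameters = list()) {
  name <- match.arg(name)
  task <- match.arg(task)
  defaults <- switch(name,
    RF = list(num_trees = 500),
    SVM = list(kernel = "linear", cost = 1),
    XGBoost = list(nrounds = 100, eta = 0.3, max_depth = 6),
    external = list())
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(name = name, task = task, seed = as.integer(seed),
                 hyperparameters = hp),
            class = "model_spec")
}

new_prediction_set <- function(df, dataset, model, representation, method,
                               seed, task, partition = "test", subset = "all",
                               extra = list()) {
  structure(df, class = c("prediction_set", "data.frame"),
            dataset = dataset, model = model, representation = representation,
            method = method, seed = seed, task = task, partition = partition,
            subset = subset, provenance = extra)
}

# data.frame subsetting drops custom attributes; restore them on a view.
restore_prediction_set <- function(view, orig, subset = NULL) {
  new_prediction_set(as.data.frame(view),
                     attr(orig, "dataset"), attr(orig, "model"),
                     attr(orig, "representation"), attr(orig, "method"),
                     attr(orig, "seed"), attr(orig, "task"),
                     attr(orig, "partition"),
                     subset %||% attr(orig, "subset"),
                     attr(orig, "provenance"))
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set %s/%s/%s/%s seed=%s subset=%s> %d molecules\n",
              attr(x, "dataset"), attr(x, "model"), attr(x, "representation"),
              attr(x, "method"), attr(x, "seed"), attr(x, "subset"), nrow(x)))
  invisible(x)
}

fit_predict_backend <- function(spec, x_train, y_train, x_test) {
  hp <- spec$hyperparameters
  if (spec$name == "RF") {
    if (spec$task == "classification") {
      fit <- ranger::ranger(x = x_train, y = factor(y_train, levels = c(0, 1)),
                            num.trees = hp$num_trees, probability = TRUE,
                            seed = spec$seed, num.threads = 1, verbose = FALSE)
      stats::predict(fit, data = x_test, num.threads = 1)$predictions[, "1"]
    } else {
      fit <- ranger::ranger(x = x_train, y = y_train, num.trees = hp$num_trees,
                            seed = spec$seed, num.threads = 1, verbose = FALSE)
      stats::predict(fit, data = x_test, num.threads = 1)$predictions
    }
  } else if (spec$name == "SVM") {
    if (spec$task == "classification") {
      fit <- e1071::svm(x = x_train, y = factor(y_train, levels = c(0, 1)),
                        kernel = "linear", cost = hp$cost, scale = FALSE)
      dvm <- attr(stats::predict(fit, x_test, decision.values = TRUE),
                  "decision.values")
      dv <- dvm[, 1]
      # decision values are signed toward the class named first in "A/B";
      # orient them toward the positive class before min-max scaling
      if (startsWith(colnames(dvm)[1], "0/")) dv <- -dv
      rng <- range(dv)
      if (diff(rng) == 0) rep(0.5, length(dv)) else (dv - rng[1]) / diff(rng)
    } else {
      fit <- e1071::svm(x = x_train, y = y_train, kernel = "linear",
                        cost = hp$cost, scale = FALSE)
      as.numeric(stats::predict(fit, x_test))
    }
  } else if (spec$name == "XGBoost") {
    obj <- if (spec$task == "classification") "binary:logistic" else "reg:squarederror"
    dtrain <- xgboost::xgb.DMatrix(x_train, label = y_train, nthread = 1)
    fit <- withr::with_seed(spec$seed,
      xgboost::xgb.train(params = list(objective = obj, eta = hp$eta,
                                       max_depth = hp$max_depth, nthread = 1,
                                       seed = spec$seed),
                         data = dtrain, nrounds = hp$nrounds, verbose = 0))
    stats::predict(fit, xgboost::xgb.DMatrix(x_test, nthread = 1))
  } else {
    stop("model '", spec$name, "' has no training backend")
  }
}

#' Train a baseline model and predict the test partition
#'
#' Fits on the training partition only (the validation ids are kept in the
#' manifest for model plug-ins but are unused by the traditional baselines)
#' and emits raw predictions for the test partition. Test labels are never
#' passed to the fitting call. Deterministic given the model seed.
#'
#' @param spec A `model_spec` (not "external").
#' @param features A `feature_matrix` covering all manifest ids.
#' @param dataset The `curated_dataset` holding the labels.
#' @param manifest A `split_manifest`.
#' @return A `prediction_set` data.frame (id, y_true and `pred` for
#'   regression or `score` in \[0,1\] for classification) with full
#'   provenance attributes.
#' @export
train_and_predict <- function(spec, features, dataset, manifest) {
  stopifnot(inherits(spec, "model_spec"), inherits(manifest, "split_manifest"))
  if (spec$name == "external") stop("use external_predictions() for external models")
  if (spec$task != dataset$task) {
    stop("model task (", spec$task, ") does not match dataset task (",
         dataset$task, ")")
  }
  all_ids <- c(manifest$train_ids, manifest$val_ids, manifest$test_ids)
  missing_ids <- setdiff(all_ids, rownames(features))
  if (length(missing_ids)) {
    stop("feature matrix does not cover manifest ids: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  labels <- stats::setNames(dataset$data$label, dataset$data$id)
  y_train <- labels[manifest$train_ids]
  if (spec$task == "classification" && length(unique(y_train)) < 2) {
    stop("degenerate single-class training set")
  }
  x_train <- unclass(features)[manifest$train_ids, , drop = FALSE]
  x_test <- unclass(features)[manifest$test_ids, , drop = FALSE]
  out <- fit_predict_backend(spec, x_train, unname(y_train), x_test)
  df <- data.frame(id = manifest$test_ids,
                   y_true = unname(labels[manifest$test_ids]),
                   stringsAsFactors = FALSE)
  if (spec$task == "classification") df$score <- out else df$pred <- out
  new_prediction_set(df, dataset$name, spec$name,
                     attr(features, "representation"), manifest$method,
                     manifest$seed, spec$task,
                     extra = list(hyperparameters = spec$hyperparameters,
                                  model_seed = spec$seed))
}

#' Wrap externally produced predictions as a prediction set
#'
#' Lets predictions from any outside model (e.g. a pretrained deep net)
#' enter the metric and statistics layers.
#'
#' @param df data.frame with columns id, y_true and pred (regression) or
#'   score (classification).
#' @param dataset,model,representation,method,seed,task Provenance fields.
#' @return A `prediction_set`.
#' @export
external_predictions <- function(df, dataset = "external", model = "external",
                                 representation = "external",
                                 method = "external", seed = NA_integer_,
                                 task = c("regression", "classification")) {
  task <- match.arg(task)
  need <- c("id", "y_true", if (task == "regression") "pred" else "score")
  stopifnot(all(need %in% names(df)))
  new_prediction_set(df[need], dataset, model, representation, method, seed, task)
}

#' Write a prediction set to CSV with a JSON provenance sidecar
#' @param pred A `prediction_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(pred), path, row.names = FALSE)
  jsonlite::write_json(
    list(dataset = attr(pred, "dataset"), model = attr(pred, "model"),
         representation = attr(pred, "representation"),
         method = attr(pred, "method"), seed = attr(pred, "seed"),
         task = attr(pred, "task"), partition = attr(pred, "partition"),
         subset = attr(pred, "subset"), provenance = attr(pred, "provenance")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
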