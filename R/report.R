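#' Assemble a study report from persisted benchmark artifacts
#'
#' Aggregates only from the artifacts in a [run_benchmark()] output
#' directory: per-(model, representation, method, subset, metric) mean and
#' standard deviation over seeds, with every expected grid cell either
#' present or surfaced as an explicit gap. Optional AC-annotation files add
#' a Table-1-style cliff summary.
#'
#' @param artifact_dir Directory written by [run_benchmark()].
#' @return A `study_report` list with `summary` (aggregated metric table),
#'   `per_seed` (the raw metric rows), `gaps` (missing cells) and
#'   `ac_summary` (if an annotation summary was persisted there).
#' @export
build_report <- function(artifact_dir) {
  if (!dir.exists(artifact_dir)) stop("artifact directory does not exist")
  metrics_path <- file.path(artifact_dir, "metrics.csv")
  if (!file.exists(metrics_path)) stop("no metrics.csv under ", artifact_dir)
  metrics <- utils::read.csv(metrics_path, stringsAsFactors = FALSE)

  key_cols <- c("dataset", "model", "representation", "method", "subset",
                "metric")
  agg <- stats::aggregate(value ~ dataset + model + representation + method +
                            subset + metric, data = metrics,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n_seeds = length(v)))
  summary <- cbind(agg[key_cols], as.data.frame(agg$value))

  gaps <- NULL
  grid_path <- file.path(artifact_dir, "grid.json")
  if (file.exists(grid_path)) {
    grid <- jsonlite::read_json(grid_path, simplifyVector = TRUE)
    have <- nrow(unique(metrics[metrics$subset == "all",
                                c("model", "representation", "method", "seed")]))
    if (have < grid$n_cells) {
      gaps <- data.frame(expected = grid$n_cells, present = have,
                         missing = grid$n_cells - have)
    }
  }

  ac_path <- list.files(artifact_dir, pattern = "_summary\\.json$",
                        full.names = TRUE)
  ac_summary <- if (length(ac_path)) {
    jsonlite::read_json(ac_path[1], simplifyVector = TRUE)
  } else NULL

  structure(list(summary = summary, per_seed = metrics, gaps = gaps,
                 ac_summary = ac_summary),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", nrow(x$summary), "aggregated metric rows\n")
  if (!is.null(x$gaps)) {
    cat("  gaps:", x$gaps$missing, "of", x$gaps$expected, "cells missing\n")
  }
  invisible(x)
}

#' Write a study report as JSON (+ summary CSV)
#'
#' @param report A `study_report`.
#' @param path Output JSON path; the summary table also goes to
#'   `<path>.summary.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(summary = report$summary, gaps = report$gaps,
         ac_summary = report$ac_summary),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(report$summary, paste0(path, ".summary.csv"),
                   row.names = FALSE)
  invisible(path)
}
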