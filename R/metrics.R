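check_binary_labels <- function(labels) {
  if (!length(labels)) stop("empty label vector")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2) stop("both classes must be present")
}

#' Youden-J-optimal classification threshold
#'
#' Maximizes J = TPR - FPR over all distinct score values used as cut
#' points (a molecule is called positive when its score is >= the
#' threshold). Ties in J are broken toward the higher threshold, the
#' conservative operating point.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return The selected threshold (one of the score values).
#' @export
youden_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  check_binary_labels(labels)
  cand <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  # exact integer comparison: J = TP/n_pos - FP/n_neg ranks cut points the
  # same way as TP*n_neg - FP*n_pos, without float round-off breaking ties
  j_num <- vapply(cand, function(t) {
    pos <- scores >= t
    sum(pos & labels == 1) * n_neg - sum(pos & labels == 0) * n_pos
  }, numeric(1))
  cand[which.max(j_num)]  # candidates descend: first max = highest threshold
}

#' Confusion counts at a threshold
#'
#' @inheritParams youden_threshold
#' @param threshold Scores >= threshold are predicted positive.
#' @return List with TP, FP, TN, FN and the threshold.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  pos <- scores >= threshold
  list(TP = sum(pos & labels == 1), FP = sum(pos & labels == 0),
       TN = sum(!pos & labels == 0), FN = sum(!pos & labels == 1),
       threshold = threshold)
}

# Rank (Mann-Whitney) AUROC with half-credit for ties.
auroc <- function(scores, labels) {
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  u <- sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2
  u / (n_pos * n_neg)
}

# Average precision (step-wise integral of the PR curve, no interpolation).
auprc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)  # one operating point per distinct score
  tp <- tp[last]; fp <- fp[last]
  n_pos <- sum(labels == 1)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Classification metric suite
#'
#' AUROC (rank formulation, half-credit ties), AUPRC (average precision),
#' and PPV = TP/(TP+FP), NPV = TN/(TN+FN) at a fixed threshold. Threshold
#' policy: an explicit `threshold` wins; otherwise the Youden-J threshold is
#' used when the minority-class fraction is below 0.4 (imbalanced data),
#' else 0.5. Zero-denominator PPV/NPV are `NA` (undefined), never 0.
#'
#' @inheritParams youden_threshold
#' @param threshold Optional explicit threshold.
#' @return List with `metrics` (named vector AUROC/AUPRC/PPV/NPV),
#'   `confusion` (see [confusion_counts()]), `threshold`,
#'   `threshold_policy` and `n`.
#' @export
classification_metrics <- function(scores, labels, threshold = NULL) {
  stopifnot(length(scores) == length(labels))
  check_binary_labels(labels)
  if (!is.null(threshold)) {
    policy <- "explicit"
  } else if (min(mean(labels == 1), mean(labels == 0)) < 0.4) {
    threshold <- youden_threshold(scores, labels)
    policy <- "youden"
  } else {
    threshold <- 0.5
    policy <- "fixed_0.5"
  }
  cc <- confusion_counts(scores, labels, threshold)
  ppv <- if (cc$TP + cc$FP == 0) NA_real_ else cc$TP / (cc$TP + cc$FP)
  npv <- if (cc$TN + cc$FN == 0) NA_real_ else cc$TN / (cc$TN + cc$FN)
  list(metrics = c(AUROC = auroc(scores, labels),
                   AUPRC = auprc(scores, labels),
                   PPV = ppv, NPV = npv),
       confusion = cc, threshold = threshold, threshold_policy = policy,
       n = length(labels))
}

#' Regression metric suite
#'
#' RMSE, MAE, R2 (coefficient of determination against the label-mean
#' baseline; can be negative) and the Pearson correlation between
#' predictions and labels (`NA` when either vector is constant).
#'
#' @param preds,labels Equal-length numeric vectors, n >= 2.
#' @return List with `metrics` (named vector RMSE/MAE/R2/Pearson_R) and `n`.
#' @export
regression_metrics <- function(preds, labels) {
  if (length(preds) != length(labels)) stop("length mismatch")
  if (length(labels) < 2) stop("need at least 2 observations")
  err <- labels - preds
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  ss_tot <- sum((labels - mean(labels))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(err^2) / ss_tot
  pr <- if (stats::sd(preds) == 0 || stats::sd(labels) == 0) NA_real_ else
    stats::cor(preds, labels)
  list(metrics = c(RMSE = rmse, MAE = mae, R2 = r2, Pearson_R = pr),
       n = length(labels))
}

#' Evaluate a prediction set with the appropriate metric suite
#'
#' @param pred A `prediction_set`.
#' @param threshold Optional explicit classification threshold.
#' @return A one-row-per-metric data.frame with provenance columns
#'   (dataset, model, representation, method, seed, subset, metric, value,
#'   threshold, n).
#' @export
evaluate_predictions <- function(pred, threshold = NULL) {
  stopifnot(inherits(pred, "prediction_set"))
  task <- attr(pred, "task")
  if (task == "classification") {
    res <- classification_metrics(pred$score, pred$y_true, threshold)
    thr <- res$threshold
  } else {
    res <- regression_metrics(pred$pred, pred$y_true)
    thr <- NA_real_
  }
  data.frame(dataset = attr(pred, "dataset") %||% NA_character_,
             model = attr(pred, "model") %||% NA_character_,
             representation = attr(pred, "representation") %||% NA_character_,
             method = attr(pred, "method") %||% NA_character_,
             seed = attr(pred, "seed") %||% NA_integer_,
             subset = attr(pred, "subset") %||% "all",
             metric = names(res$metrics),
             value = unname(res$metrics),
             threshold = thr,
             n = res$n,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
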