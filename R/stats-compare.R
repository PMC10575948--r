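# Null distribution counts of the Mann-Whitney U statistic by the standard
# recurrence c(m, n, u) = c(m-1, n, u-n) + c(m, n-1, u); returned as the
# vector of counts for u = 0..m*n.
mw_u_counts <- function(m, n) {
  counts <- matrix(list(), m + 1, n + 1)
  for (i in 0:m) {
    for (j in 0:n) {
      if (i == 0 || j == 0) {
        counts[[i + 1, j + 1]] <- 1
      } else {
        a <- counts[[i, j + 1]]       # last element from sample A: u - j
        b <- counts[[i + 1, j]]       # last element from sample B
        a <- c(rep(0, j), a)
        length(a) <- i * j + 1
        length(b) <- i * j + 1
        a[is.na(a)] <- 0; b[is.na(b)] <- 0
        counts[[i + 1, j + 1]] <- a + b
      }
    }
  }
  counts[[m + 1, n + 1]]
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from ranks for the first sample. The null p-value uses
#' exact enumeration of the U distribution when the combined sample size is
#' at most 16 and no ties are present; otherwise the normal approximation
#' with tie correction and continuity correction is used (the path is
#' reported).
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `U` (for sample `a`), `p` (two-sided), and `method`
#'   ("exact" or "normal").
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("samples must be non-empty")
  m <- length(a); n <- length(b)
  r <- rank(c(a, b), ties.method = "average")
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (m + n <= 16 && !ties) {
    counts <- mw_u_counts(m, n)
    total <- sum(counts)
    cdf <- cumsum(counts) / total
    sf <- rev(cumsum(rev(counts))) / total   # P(U >= u)
    p <- min(1, 2 * min(cdf[u + 1], sf[u + 1]))
    return(list(U = u, p = p, method = "exact"))
  }
  mu <- m * n / 2
  nt <- m + n
  tie_tab <- table(c(a, b))
  tie_term <- sum(tie_tab^3 - tie_tab) / (nt * (nt - 1))
  sigma2 <- m * n / 12 * (nt + 1 - tie_term)
  if (sigma2 <= 0) return(list(U = u, p = 1, method = "normal"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(U = u, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Pairwise model comparison over identical seed sets
#'
#' Runs the two-sided Mann-Whitney U test on every unordered pair of model
#' metric vectors and flags pairs with p < alpha. No multiple-testing
#' correction is applied by default (set `adjust` to a [p.adjust()] method
#' to enable one).
#'
#' @param results Named list (or seeds-by-models matrix) of per-seed metric
#'   values; all models must cover the same seeds.
#' @param alpha Significance level (default 0.05).
#' @param adjust Optional p-value adjustment method passed to [p.adjust()];
#'   default "none".
#' @return List with `p_matrix` (symmetric, diagonal 1), `significant`
#'   (logical matrix), `means`, `sds` and `alpha`.
#' @export
pairwise_compare <- function(results, alpha = 0.05, adjust = "none") {
  if (is.matrix(results)) {
    results <- as.data.frame(results)
  }
  results <- lapply(results, as.numeric)
  k <- length(results)
  models <- names(results)
  if (is.null(models)) models <- paste0("model", seq_len(k))
  n_seeds <- unique(lengths(results))
  if (length(n_seeds) != 1) stop("all models must be evaluated on identical seed sets")
  p <- matrix(1, k, k, dimnames = list(models, models))
  if (k >= 2) {
    idx <- utils::combn(k, 2)
    raw <- apply(idx, 2, function(ij) mann_whitney_u(results[[ij[1]]], results[[ij[2]]])$p)
    raw <- stats::p.adjust(raw, method = adjust)
    for (c_i in seq_len(ncol(idx))) {
      i <- idx[1, c_i]; j <- idx[2, c_i]
      p[i, j] <- p[j, i] <- raw[c_i]
    }
  }
  list(p_matrix = p, significant = p < alpha & row(p) != col(p),
       means = vapply(results, mean, numeric(1)),
       sds = vapply(results, stats::sd, numeric(1)),
       alpha = alpha)
}

#' Count single-fold and triple-combination wins
#'
#' Single mode: for each seed, the model with the best metric value wins;
#' exact ties (to relative tolerance 1e-12) award no model and are counted
#' separately. Triple mode: over all C(seeds, 3) seed combinations, the
#' model with the best mean over the triple wins.
#'
#' @param metric_table Seeds-by-models numeric matrix (complete, no NA).
#' @param mode "single" or "triple".
#' @param better "higher" (e.g. AUROC) or "lower" (e.g. RMSE).
#' @return List with per-model `wins` and the number of `ties`.
#' @export
count_wins <- function(metric_table, mode = c("single", "triple"),
                       better = c("higher", "lower")) {
  mode <- match.arg(mode); better <- match.arg(better)
  metric_table <- as.matrix(metric_table)
  if (anyNA(metric_table)) stop("metric table has missing cells")
  if (is.null(colnames(metric_table))) {
    colnames(metric_table) <- paste0("model", seq_len(ncol(metric_table)))
  }
  sgn <- if (better == "higher") 1 else -1
  score_rows <- if (mode == "single") {
    sgn * metric_table
  } else {
    combos <- utils::combn(nrow(metric_table), 3)
    t(apply(combos, 2, function(tr) sgn * colMeans(metric_table[tr, , drop = FALSE])))
  }
  wins <- stats::setNames(rep(0L, ncol(metric_table)), colnames(metric_table))
  ties <- 0L
  for (i in seq_len(nrow(score_rows))) {
    v <- score_rows[i, ]
    best <- max(v)
    tol <- 1e-12 * max(1, abs(best))
    top <- which(v >= best - tol)
    if (length(top) == 1) wins[top] <- wins[top] + 1L else ties <- ties + 1L
  }
  list(wins = wins, ties = ties)
}

#' Zero out non-significant performance differences
#'
#' @param diffs Numeric differences (e.g. scaffold-minus-random mean RMSE).
#' @param ps Matching two-sided p-values.
#' @param alpha Significance level (default 0.05).
#' @return `diffs` with entries at p >= alpha imputed as zero.
#' @export
impute_nonsignificant <- function(diffs, ps, alpha = 0.05) {
  if (length(diffs) != length(ps)) stop("length mismatch")
  ifelse(ps < alpha, diffs, 0)
}

#' Metric variability analysis across models
#'
#' Per-model standard deviation of a metric over seeds, and the Pearson
#' correlation between model means and model standard deviations — the
#' diagnostic that noisier models also tend to be worse.
#'
#' @param results Named list or seeds-by-models matrix of per-seed metric
#'   values (>= 3 models, >= 2 seeds).
#' @return List with `means`, `sds` and `cor_mean_sd` (`NA` when all sds are
#'   equal, i.e. zero variance).
#' @export
variability_analysis <- function(results) {
  if (is.matrix(results)) results <- as.data.frame(results)
  if (length(results) < 3) stop("need at least 3 models")
  if (any(lengths(results) < 2)) stop("need at least 2 seeds per model")
  means <- vapply(results, mean, numeric(1))
  sds <- vapply(results, stats::sd, numeric(1))
  cor_mean_sd <- if (stats::sd(sds) == 0 || stats::sd(means) == 0) NA_real_ else
    stats::cor(means, sds)
  list(means = means, sds = sds, cor_mean_sd = cor_mean_sd)
}

#' Residual analysis of a regression prediction set
#'
#' Signed errors (prediction minus label), the least-squares slope of error
#' on label (systematic over/under-estimation trend), and mean error within
#' an optional flagged subset (e.g. edge cases).
#'
#' @param pred A regression `prediction_set`.
#' @param subset_ids Optional ids whose mean error is reported separately.
#' @return List with `errors` (named by id), `slope` (`NA` when n < 3 or
#'   labels are constant) and `subset_mean_error`.
#' @export
residual_analysis <- function(pred, subset_ids = NULL) {
  stopifnot(inherits(pred, "prediction_set"))
  if (attr(pred, "task") != "regression") stop("needs regression predictions")
  err <- pred$pred - pred$y_true
  names(err) <- pred$id
  slope <- if (length(err) < 3 || stats::sd(pred$y_true) == 0) NA_real_ else
    stats::cov(err, pred$y_true) / stats::var(pred$y_true)
  subset_mean <- if (is.null(subset_ids)) NULL else mean(err[names(err) %in% subset_ids])
  list(errors = err, slope = slope, subset_mean_error = subset_mean)
}
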