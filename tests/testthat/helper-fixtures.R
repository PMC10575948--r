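# Shared fixtures, built once per test session (chemistry results are also
# cached inside the package, so repeated generator calls stay cheap).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# default opioid-like synthetic dataset + ground truth
synth_default <- function(seed = 1) {
  fixture(paste0("synth_", seed), function() {
    generate_activity_dataset(synthetic_spec(seed = seed))
  })
}

# small dataset for model tests: fewer scaffolds, quick to featurize
synth_small <- function(seed = 7) {
  fixture(paste0("small_", seed), function() {
    generate_activity_dataset(synthetic_spec(
      n_scaffolds = 40, molecules_per_scaffold = c(3, 6),
      ac_group_size = c(8, 12), seed = seed))
  })
}

morgan_small <- function() {
  fixture("morgan_small", function() {
    compute_representation("MorganBits", synth_small()$dataset)
  })
}

# a pool of valid canonical SMILES for property tests
smiles_pool <- function(n = 1000, seed = 42) {
  pool <- fixture("pool", function() generate_descriptor_dataset(3000, "MolWt", seed = 99))
  withr::with_seed(seed, sample(pool$data$smiles, n))
}

# brute-force metric oracles, independent of the package implementations
oracle_rmse <- function(p, y) sqrt(sum((y - p)^2) / length(y))
oracle_mae <- function(p, y) sum(abs(y - p)) / length(y)
oracle_r2 <- function(p, y) 1 - sum((y - p)^2) / sum((y - mean(y))^2)
oracle_pearson <- function(p, y) {
  sum((y - mean(y)) * (p - mean(p))) /
    sqrt(sum((y - mean(y))^2) * sum((p - mean(p))^2))
}
# pairwise-comparison AUROC: P(score_pos > score_neg) + 0.5 P(equal)
oracle_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
# average precision by explicit threshold sweep
oracle_auprc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0; prev_recall <- 0
  for (t in ths) {
    pos <- scores >= t
    tp <- sum(pos & labels == 1)
    prec <- tp / sum(pos)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * prec
    prev_recall <- recall
  }
  ap
}
oracle_ppv_npv <- function(scores, labels, threshold) {
  pos <- scores >= threshold
  tp <- sum(pos & labels == 1); fp <- sum(pos & labels == 0)
  tn <- sum(!pos & labels == 0); fn <- sum(!pos & labels == 1)
  c(ppv = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    npv = if (tn + fn == 0) NA_real_ else tn / (tn + fn))
}
# exhaustive Youden argmax over distinct score cut points; ties resolved
# toward the higher threshold via exact fraction comparison (cross-multiplied
# so equal J values are recognized as equal)
oracle_youden <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  best_num <- -Inf; best_t <- NA_real_
  for (t in sort(unique(scores))) {  # ascending: later >= winners are higher
    pos <- scores >= t
    num <- sum(pos & labels == 1) * n0 - sum(pos & labels == 0) * n1
    if (num >= best_num) { best_num <- num; best_t <- t }
  }
  best_t
}
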