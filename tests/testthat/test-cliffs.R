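cliff_toy <- function(labels_by_scaffold) {
  # build a curated dataset with specified per-scaffold label vectors,
  # bypassing chemistry (scaffold strings are opaque group keys here)
  rows <- do.call(rbind, lapply(names(labels_by_scaffold), function(sc) {
    v <- labels_by_scaffold[[sc]]
    data.frame(scaffold = sc, label = v, stringsAsFactors = FALSE)
  }))
  rows$id <- sprintf("T%03d", seq_len(nrow(rows)))
  rows$smiles <- rows$id; rows$smiles_raw <- rows$id
  rows$smiles_length <- nchar(rows$id)
  qsareval:::new_curated_dataset("toy", "regression", rows)
}

test_that("the cliff span threshold is inclusive at two log units", {
  d <- cliff_toy(list(a = c(5.0, 7.0), b = c(5.0, 6.9), c = 5.0))
  ann <- annotate_cliffs(d)
  spans <- setNames(ann$scaffolds$span, ann$scaffolds$scaffold)
  expect_equal(unname(spans[c("a", "b", "c")]), c(2.0, 1.9, 0))
  expect_identical(ann$scaffolds$is_ac[match(c("a", "b", "c"),
                                             ann$scaffolds$scaffold)],
                   c(TRUE, FALSE, FALSE))  # inclusive >= 2; singletons never AC
  expect_equal(ann$summary$ac_scaffold_pct, 100 / 3)
  expect_equal(ann$summary$ac_molecules, 2)
  expect_error(annotate_cliffs(binarize(d)), "regression")
})

test_that("edge groups must straddle the cutoff inside the window", {
  d <- cliff_toy(list(a = c(5.5, 6.5), b = c(5.5, 5.9), c = c(4.0, 8.0),
                      e = c(4.5, 5.5, 6.5)))
  ed <- find_edge_cases(d)
  flag <- split(ed$is_edge, ed$scaffold)
  expect_true(all(flag$a))          # both sides of 6 within [5,7]
  expect_false(any(flag$b))         # one side only
  expect_false(any(flag$c))         # nothing inside the window
  expect_identical(flag$e, c(FALSE, TRUE, TRUE))  # 4.5 outside the window
  expect_error(find_edge_cases(d, window = c(5, 7), cutoff = 8), "window")
})

test_that("edge flags are invariant to molecule ordering", {
  d <- cliff_toy(list(a = c(5.5, 6.5, 5.1), b = c(6.2, 6.4), c = c(5.2, 6.8)))
  ed1 <- find_edge_cases(d)
  d2 <- d; d2$data <- d2$data[rev(seq_len(nrow(d2$data))), ]
  ed2 <- find_edge_cases(d2)
  expect_identical(ed1$is_edge[match(ed2$id, ed1$id)], ed2$is_edge)
})

test_that("planted cliffs are recovered exactly at zero noise", {
  out <- synth_default()
  ann <- annotate_cliffs(out$dataset)
  planted <- out$ground_truth$scaffolds$scaffold[out$ground_truth$scaffolds$is_ac]
  found <- ann$scaffolds$scaffold[ann$scaffolds$is_ac]
  expect_setequal(found, planted)
  # every AC scaffold needs >= 2 members
  expect_gte(ann$summary$ac_molecules, 2 * ann$summary$ac_scaffolds)
})

test_that("prediction stratification partitions by AC status and drops edges", {
  out <- synth_default()
  d <- out$dataset
  ann <- annotate_cliffs(d)
  gt_edge <- data.frame(id = out$ground_truth$molecules$id,
                        is_edge = out$ground_truth$molecules$is_edge)
  pred <- external_predictions(
    data.frame(id = d$data$id, y_true = d$data$label, pred = d$data$label),
    task = "regression")
  views <- stratify_predictions(pred, ann, edge = gt_edge)
  expect_setequal(c(views$ac$id, views$non_ac$id), views$all$id)
  expect_length(intersect(views$ac$id, views$non_ac$id), 0)
  expect_setequal(views$ac$id,
                  out$ground_truth$molecules$id[out$ground_truth$molecules$is_ac])
  expect_equal(nrow(views$edge_removed), nrow(pred) - sum(gt_edge$is_edge))
  expect_equal(attr(views$ac, "subset"), "ac")

  bad <- external_predictions(
    data.frame(id = "nope", y_true = 1, pred = 1), task = "regression")
  expect_error(stratify_predictions(bad, ann), "nope")
})

test_that("a dataset without cliffs yields an empty AC view", {
  d <- cliff_toy(list(a = c(5.5, 6.0), b = c(6.2, 6.4)))
  ann <- annotate_cliffs(d)
  pred <- external_predictions(
    data.frame(id = d$data$id, y_true = d$data$label, pred = d$data$label),
    task = "regression")
  views <- stratify_predictions(pred, ann)
  expect_equal(nrow(views$ac), 0)
  expect_setequal(views$non_ac$id, views$all$id)
})

test_that("cliff-burden correlation behaves at its boundary cases", {
  frac <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(ac_burden_correlation(2 * frac + 1, frac), 1.0)
  expect_true(is.na(ac_burden_correlation(c(1, 2, 3), rep(0.5, 3))))
  expect_error(ac_burden_correlation(1:3, 1:4), "mismatch")
  expect_error(ac_burden_correlation(1:2, 1:2), "at least 3")
})

test_that("per-partition AC fractions derive from manifests", {
  out <- synth_default()
  ann <- annotate_cliffs(out$dataset)
  m <- scaffold_split(out$dataset, seed = 2)
  fr <- ac_fraction(m, ann)
  expect_named(fr, c("train", "val", "test"))
  expect_true(all(fr >= 0 & fr <= 1))
  n <- n_molecules(out$dataset)
  w <- lengths(m[c("train_ids", "val_ids", "test_ids")]) / n
  expect_equal(unname(sum(fr * w)), ann$summary$ac_molecules / n)
})
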