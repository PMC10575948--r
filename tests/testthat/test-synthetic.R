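test_that("generation is fully determined by the seed", {
  s <- synthetic_spec(n_scaffolds = 30, seed = 5)
  a <- generate_activity_dataset(s)
  b <- generate_activity_dataset(synthetic_spec(n_scaffolds = 30, seed = 5))
  expect_identical(a$dataset$data, b$dataset$data)
  expect_identical(a$ground_truth, b$ground_truth)
  c2 <- generate_activity_dataset(synthetic_spec(n_scaffolds = 30, seed = 6))
  expect_false(identical(a$dataset$data$label, c2$dataset$data$label))
})

test_that("every generated SMILES is valid, canonical and ring-bearing", {
  out <- synth_default()
  d <- out$dataset
  res <- canonicalize(d$data$smiles)
  expect_true(all(res$valid))
  expect_identical(res$canonical, d$data$smiles)      # already canonical
  expect_true(all(nzchar(d$data$scaffold)))           # scaffolds are rings
  expect_identical(murcko_scaffold(d$data$smiles), d$data$scaffold)
  expect_equal(anyDuplicated(d$data$smiles), 0)       # one record per molecule
})

test_that("ground-truth labels reproduce exactly from base + effects", {
  gt <- synth_default()$ground_truth$molecules
  expect_equal(gt$noiseless_label, gt$base + gt$effect, tolerance = 0)
  sc <- synth_default()$ground_truth$scaffolds
  spans <- tapply(gt$noiseless_label, gt$scaffold, function(v) max(v) - min(v))
  expect_true(all(spans[sc$scaffold[sc$is_ac]] >= 2.5))   # planted magnitude
  expect_true(all(spans[sc$scaffold[!sc$is_ac]] < 2.0))   # below AC threshold
})

test_that("the Table-1 shape emerges: few AC scaffolds, many AC molecules", {
  out <- synth_default()
  ann <- annotate_cliffs(out$dataset)
  expect_equal(ann$summary$ac_scaffold_pct, 10, tolerance = 0.25)
  expect_gt(ann$summary$ac_molecule_pct, 30)
  expect_lt(ann$summary$ac_molecule_pct, 50)
})

test_that("positive rate calibration hits its target", {
  out <- fixture("synth_big", function() {
    generate_activity_dataset(synthetic_spec(
      n_scaffolds = 200, molecules_per_scaffold = c(8, 12),
      ac_group_size = c(15, 20), target_positive_rate = 0.3, seed = 17))
  })
  d <- out$dataset
  expect_gte(n_molecules(d), 2000)
  expect_equal(mean(d$data$label >= 6), 0.3, tolerance = 0.03)
  expect_gt(qsareval:::skewness_coef(d$data$label), 0)  # right skew requested
})

test_that("edge groups straddle the cutoff inside the 5-7 window", {
  out <- synth_default()
  gt <- out$ground_truth
  edge_sc <- gt$scaffolds$scaffold[gt$scaffolds$is_edge_group]
  expect_gt(length(edge_sc), 0)
  for (sc in edge_sc) {
    v <- gt$molecules$noiseless_label[gt$molecules$scaffold == sc]
    expect_true(all(v >= 5 & v <= 7))
    expect_true(any(v < 6) && any(v >= 6))
  }
  flagged <- find_edge_cases(out$dataset)
  planted <- gt$molecules$id[gt$molecules$is_edge]
  expect_true(all(planted %in% flagged$id[flagged$is_edge]))
})

test_that("cliff recovery degrades gracefully with label noise", {
  recall_at <- function(sigma) {
    base <- synthetic_spec(n_scaffolds = 60, seed = 11)
    out <- generate_activity_dataset(base)
    d <- out$dataset
    if (sigma > 0) {
      d <- add_label_noise(d, list(type = "gaussian", sd = sigma), seed = 11)
    }
    ann <- annotate_cliffs(d)
    planted <- out$ground_truth$scaffolds$scaffold[out$ground_truth$scaffolds$is_ac]
    mean(planted %in% ann$scaffolds$scaffold[ann$scaffolds$is_ac])
  }
  r <- vapply(c(0, 0.3, 0.6), recall_at, numeric(1))
  expect_equal(r[1], 1.0)
  expect_true(all(diff(r) <= 0))  # monotone non-increasing in noise
})

test_that("label noise matches its nominal model", {
  out <- fixture("synth_big", function() {
    generate_activity_dataset(synthetic_spec(
      n_scaffolds = 200, molecules_per_scaffold = c(8, 12),
      ac_group_size = c(15, 20), target_positive_rate = 0.3, seed = 17))
  })
  d <- out$dataset
  same <- add_label_noise(d, list(type = "none"))
  expect_identical(same$data$label, d$data$label)

  big <- generate_descriptor_dataset(10000, "MolWt", seed = 2)
  big$data$label <- withr::with_seed(1, rnorm(10000, 6, 1))
  noisy <- add_label_noise(big, list(type = "gaussian", sd = 0.5), seed = 3)
  delta <- noisy$data$label - big$data$label
  expect_gte(sd(delta), 0.48); expect_lte(sd(delta), 0.52)
  expect_identical(unname(noisy$clean_labels), big$data$label)

  het <- add_label_noise(big, list(type = "heteroscedastic", sd = 0.1,
                                   k = 0.3, y0 = 6), seed = 4)
  dh <- abs(het$data$label - big$data$label)
  dist <- abs(big$data$label - 6)
  bins <- cut(dist, quantile(dist, 0:5 / 5), include.lowest = TRUE)
  spread <- tapply(dh, bins, sd)
  expect_gt(cor(seq_along(spread), spread, method = "spearman"), 0)
  expect_error(add_label_noise(big, list(type = "gaussian", sd = -1)), "negative")
})

test_that("descriptor datasets have labels recomputable from structure", {
  d <- generate_descriptor_dataset(200, "NumAtoms", seed = 8)
  phys <- compute_representation("PhysChem", d)
  expect_equal(d$data$label, unname(unclass(phys)[, "NumAtoms"]), tolerance = 0)
  expect_error(generate_descriptor_dataset(5, "MolWt"), "size")
  expect_error(generate_descriptor_dataset(1e6, "MolWt"), "pool")
  expect_equal(length(ladder_sizes()), 16)
  expect_equal(range(ladder_sizes()), c(100, 100000))
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_spec(ac_scaffold_fraction = 0.5, ac_group_size = c(1, 1)),
               "at least 2")
  expect_error(generate_activity_dataset(synthetic_spec(n_scaffolds = 10000)),
               "library")
  expect_error(generate_activity_dataset(
    synthetic_spec(ac_scaffold_fraction = 0.7, edge_group_fraction = 0.7)),
    "exceed")
})
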