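test_that("regression metrics match hand-worked values", {
  r <- regression_metrics(c(3, 4), c(0, 0))$metrics
  expect_equal(unname(r["RMSE"]), sqrt(12.5))
  expect_equal(unname(r["MAE"]), 3.5)
  expect_true(is.na(r["R2"]))        # zero label variance: undefined baseline
  perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3))$metrics
  expect_equal(unname(perfect), c(0, 0, 1, 1))
  base <- regression_metrics(rep(2, 4), c(1, 2, 3, 2))$metrics
  expect_equal(unname(base["R2"]), 0)  # mean predictor is the R2 baseline
  expect_error(regression_metrics(1:3, 1:4), "mismatch")
})

test_that("classification metrics match hand-worked confusion counts", {
  # TP=3 FP=1 TN=5 FN=1 at threshold 0.5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.15, 0.1, 0.05)
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  res <- classification_metrics(scores, labels, threshold = 0.5)
  expect_equal(res$confusion[c("TP", "FP", "TN", "FN")],
               list(TP = 3L, FP = 1L, TN = 5L, FN = 1L))
  expect_equal(unname(res$metrics["PPV"]), 0.75)
  expect_equal(unname(res$metrics["NPV"]), 5 / 6, tolerance = 1e-4)

  sep <- classification_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                                threshold = 0.5)
  expect_equal(unname(sep$metrics), c(1, 1, 1, 1))

  flat <- classification_metrics(rep(0.3, 8), c(1, 0, 1, 0, 1, 0, 0, 0),
                                 threshold = 0.5)
  expect_equal(unname(flat$metrics["AUROC"]), 0.5)  # ties get half credit

  expect_error(classification_metrics(1:3 / 3, c(1, 1, 1)), "both classes")
})

test_that("threshold policy prefers explicit, then Youden for imbalance", {
  scores <- c(0.9, 0.8, 0.7, 0.2); labels <- c(1, 0, 1, 0)
  expect_equal(classification_metrics(scores, labels, threshold = 0.65)$threshold, 0.65)
  expect_equal(classification_metrics(scores, labels)$threshold_policy, "fixed_0.5")
  imb <- classification_metrics(c(0.9, 0.2, 0.3, 0.1, 0.15), c(1, 0, 0, 0, 0))
  expect_equal(imb$threshold_policy, "youden")
})

test_that("Youden threshold equals the spec example and null behavior", {
  scores <- c(0.9, 0.8, 0.7, 0.2); labels <- c(1, 0, 1, 0)
  thr <- youden_threshold(scores, labels)
  expect_equal(thr, 0.9)  # J = 0.5 tie between 0.7 and 0.9; higher wins
  j_at <- function(t) mean(scores[labels == 1] >= t) - mean(scores[labels == 0] >= t)
  expect_equal(j_at(thr), 0.5)

  sep_sc <- c(0.9, 0.8, 0.2, 0.1); sep_lab <- c(1, 1, 0, 0)
  sepd <- youden_threshold(sep_sc, sep_lab)
  expect_equal(sepd, 0.8)  # smallest positive score: J = 1 under the tie rule
  expect_equal(mean(sep_sc[sep_lab == 1] >= sepd) -
                 mean(sep_sc[sep_lab == 0] >= sepd), 1)

  withr::with_seed(1, {
    big <- youden_threshold(runif(4000), rbinom(4000, 1, 0.5))
    scores2 <- runif(4000); labels2 <- rbinom(4000, 1, 0.5)
    j <- mean(scores2[labels2 == 1] >= big) - mean(scores2[labels2 == 0] >= big)
    expect_lt(abs(j), 0.1)  # independent scores: J near zero
  })
  expect_error(youden_threshold(1:4 / 4, c(0, 0, 0, 0)), "both classes")
})

test_that("metric implementations agree with brute-force oracles", {
  withr::with_seed(101, {
    for (i in 1:300) {
      n <- sample(10:60, 1)
      y <- rnorm(n); p <- rnorm(n, mean = y / 2)
      got <- regression_metrics(p, y)$metrics
      expect_equal(unname(got["RMSE"]), oracle_rmse(p, y), tolerance = 1e-10)
      expect_equal(unname(got["MAE"]), oracle_mae(p, y), tolerance = 1e-10)
      expect_equal(unname(got["R2"]), oracle_r2(p, y), tolerance = 1e-10)
      expect_equal(unname(got["Pearson_R"]), oracle_pearson(p, y), tolerance = 1e-10)

      lab <- rbinom(n, 1, 0.4)
      if (length(unique(lab)) < 2) next
      sc <- round(runif(n), 2)  # rounding forces score ties
      cm <- classification_metrics(sc, lab, threshold = 0.5)
      expect_equal(unname(cm$metrics["AUROC"]), oracle_auroc(sc, lab), tolerance = 1e-10)
      expect_equal(unname(cm$metrics["AUPRC"]), oracle_auprc(sc, lab), tolerance = 1e-10)
      pn <- oracle_ppv_npv(sc, lab, 0.5)
      expect_equal(unname(cm$metrics["PPV"]), unname(pn["ppv"]), tolerance = 1e-10)
      expect_equal(unname(cm$metrics["NPV"]), unname(pn["npv"]), tolerance = 1e-10)
    }
  })
})

test_that("Youden threshold equals exhaustive enumeration on random inputs", {
  withr::with_seed(202, {
    for (i in 1:500) {
      n <- sample(6:40, 1)
      lab <- rbinom(n, 1, 0.5)
      if (length(unique(lab)) < 2) next
      sc <- round(runif(n), 1)
      expect_identical(youden_threshold(sc, lab), oracle_youden(sc, lab))
    }
  })
})

test_that("metric inequalities hold on random inputs", {
  withr::with_seed(303, {
    for (i in 1:200) {
      n <- sample(5:50, 1)
      y <- rnorm(n); p <- rnorm(n)
      m <- regression_metrics(p, y)$metrics
      expect_lte(m["MAE"], m["RMSE"] + 1e-12)
      if (!is.na(m["Pearson_R"])) {
        expect_lte(m["R2"], m["Pearson_R"]^2 + 1e-12)
      }
      lab <- rbinom(n, 1, 0.5)
      if (length(unique(lab)) < 2) next
      sc <- runif(n)
      u <- sum(rank(sc)[lab == 1]) - sum(lab) * (sum(lab) + 1) / 2
      expect_equal(unname(classification_metrics(sc, lab, 0.5)$metrics["AUROC"]),
                   u / (sum(lab) * sum(1 - lab)), tolerance = 1e-12)
    }
  })
})

test_that("affine rescaling preserves Pearson r but not R2", {
  withr::with_seed(9, y <- rnorm(40))
  m <- regression_metrics(2 * y + 5, y)$metrics
  expect_equal(unname(m["Pearson_R"]), 1)
  expect_lt(m["R2"], 1)
  expect_gt(m["RMSE"], 0)
})

test_that("AUROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(77, {
    for (i in 1:20) {
      n <- 80
      lab <- rbinom(n, 1, 0.4)
      if (length(unique(lab)) < 2) next
      sc <- round(rnorm(n, mean = lab), 1)
      ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                            direction = "<")))
      expect_equal(unname(classification_metrics(sc, lab, 0.5)$metrics["AUROC"]),
                   ref, tolerance = 1e-10)
    }
  })
})
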