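test_that("Mann-Whitney exact path matches enumeration landmarks", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)        # 2 * 1/C(6,3)
  expect_equal(mw$method, "exact")

  a <- c(1.5, 2.5, 3.5, 4.5)
  ident <- mann_whitney_u(a, a)  # identical multisets: ties force approx
  expect_equal(ident$U, length(a)^2 / 2)
  expect_equal(ident$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney agrees with wilcox.test on both paths", {
  withr::with_seed(31, {
    for (i in 1:30) {
      a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), mean = runif(1, -2, 2))
      mine <- mann_whitney_u(a, b)
      ref <- wilcox.test(a, b, exact = TRUE)
      expect_equal(mine$U, unname(ref$statistic))
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
    for (i in 1:30) {
      a <- round(rnorm(15), 1); b <- round(rnorm(20, 0.5), 1)  # ties likely
      mine <- mann_whitney_u(a, b)
      ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
      expect_equal(mine$method, "normal")
      expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("exact and normal-approximation p-values agree near the switchover", {
  exact_p <- function(a, b) {
    m <- length(a); u <- mann_whitney_u(a, b)$U
    counts <- qsareval:::mw_u_counts(m, length(b))
    cdf <- cumsum(counts) / sum(counts)
    sf <- rev(cumsum(rev(counts))) / sum(counts)
    min(1, 2 * min(cdf[u + 1], sf[u + 1]))
  }
  withr::with_seed(13, {
    for (i in 1:25) {
      a <- rnorm(15); b <- rnorm(15, mean = runif(1, -1, 1))
      approx <- mann_whitney_u(a, b)  # combined 30 > 16 -> normal path
      expect_equal(approx$method, "normal")
      expect_lte(abs(approx$p - exact_p(a, b)), 0.02)
    }
  })
})

test_that("Mann-Whitney type-I error is controlled at the nominal level", {
  reject <- withr::with_seed(2024, {
    vapply(1:1000, function(i) {
      mann_whitney_u(rnorm(10), rnorm(10))$p < 0.05
    }, logical(1))
  })
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("pairwise comparison flags only genuinely shifted models", {
  same <- list(A = 1:30 / 30, B = 1:30 / 30)
  cmp <- pairwise_compare(same)
  expect_false(any(cmp$significant))
  expect_equal(diag(cmp$p_matrix), c(A = 1, B = 1))
  expect_equal(cmp$p_matrix, t(cmp$p_matrix))

  withr::with_seed(8, {
    shifted <- list(A = rnorm(30), B = rnorm(30, mean = 2))
  })
  expect_true(pairwise_compare(shifted)$significant["A", "B"])

  single <- pairwise_compare(list(A = 1:30))
  expect_equal(dim(single$p_matrix), c(1, 1))
  expect_false(any(single$significant))
  expect_error(pairwise_compare(list(A = 1:30, B = 1:29)), "identical seed")
})

test_that("win counting handles dominance, ties and the triple identity", {
  tab <- cbind(A = rep(1, 30), B = rep(0, 30), C = rep(0.5, 30))
  single <- count_wins(tab, "single", "higher")
  expect_equal(single$wins, c(A = 30L, B = 0L, C = 0L))
  triple <- count_wins(tab, "triple", "higher")
  expect_equal(triple$wins, c(A = 4060L, B = 0L, C = 0L))  # C(30,3)
  expect_equal(sum(triple$wins) + triple$ties, choose(30, 3))

  tied <- cbind(A = rep(1, 30), B = rep(1, 30))
  st <- count_wins(tied, "single", "higher")
  expect_equal(st$wins, c(A = 0L, B = 0L))
  expect_equal(st$ties, 30)

  low <- count_wins(cbind(A = c(1, 1), B = c(2, 0.5)), "single", "lower")
  expect_equal(low$wins, c(A = 1L, B = 1L))
  expect_error(count_wins(cbind(A = c(1, NA))), "missing")
})

test_that("triple-combination counts match brute-force enumeration", {
  withr::with_seed(44, tab <- matrix(rnorm(30 * 3), 30, 3,
                                     dimnames = list(NULL, c("A", "B", "C"))))
  got <- count_wins(tab, "triple", "higher")
  brute <- c(A = 0L, B = 0L, C = 0L); ties <- 0L
  for (i in 1:28) for (j in (i + 1):29) for (k in (j + 1):30) {
    mu <- colMeans(tab[c(i, j, k), ])
    top <- which(mu == max(mu))
    if (length(top) == 1) brute[top] <- brute[top] + 1L else ties <- ties + 1L
  }
  expect_equal(got$wins, brute)
  expect_equal(got$ties, ties)
  expect_equal(sum(got$wins) + got$ties, 4060)

  # permutation equivariance: relabeling models permutes counts
  perm <- count_wins(tab[, c("C", "A", "B")], "triple", "higher")
  expect_equal(unname(perm$wins[c("A", "B", "C")]), unname(got$wins))
})

test_that("non-significant differences impute to zero", {
  expect_equal(impute_nonsignificant(c(0.5, 0.5), c(0.01, 0.2)), c(0.5, 0))
  expect_equal(impute_nonsignificant(c(1, 2), c(0.5, 0.9)), c(0, 0))
  expect_equal(impute_nonsignificant(c(1, 2), c(0.5, 0.9), alpha = 1), c(1, 2))
  expect_error(impute_nonsignificant(1:3, 1:2), "mismatch")
})

test_that("variability analysis correlates means with spreads", {
  det <- list(A = rep(1, 5), B = rep(2, 5), C = rep(3, 5))
  expect_true(is.na(variability_analysis(det)$cor_mean_sd))

  withr::with_seed(55, {
    noisy_worse <- lapply(c(A = 0.1, B = 0.5, C = 1.0, D = 2.0),
                          function(s) rnorm(30, mean = 2 + 3 * s, sd = s))
  })
  va <- variability_analysis(noisy_worse)
  expect_gt(va$cor_mean_sd, 0.8)  # worse models (higher RMSE-like) noisier
  expect_equal(va$cor_mean_sd, cor(va$means, va$sds), tolerance = 1e-10)
  expect_error(variability_analysis(det[1:2]), "3 models")
})

test_that("residual analysis recovers slopes and subset biases", {
  y <- c(4.5, 5.5, 6.5, 7.5)
  perfect <- external_predictions(
    data.frame(id = letters[1:4], y_true = y, pred = y), task = "regression")
  ra <- residual_analysis(perfect)
  expect_equal(unname(ra$errors), rep(0, 4))
  expect_equal(ra$slope, 0)

  meanp <- external_predictions(
    data.frame(id = letters[1:4], y_true = y, pred = rep(mean(y), 4)),
    task = "regression")
  expect_equal(residual_analysis(meanp)$slope, -1)

  over <- external_predictions(
    data.frame(id = letters[1:4], y_true = y, pred = y + c(1, 1, 0, 0)),
    task = "regression")
  expect_equal(residual_analysis(over, subset_ids = c("a", "b"))$subset_mean_error, 1)
})
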