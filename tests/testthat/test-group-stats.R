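test_that("Pearson chi-square reproduces the printed cohort p-values", {
  expect_lt(abs(pearson_chi2(rbind(c(33, 28), c(30, 34)))$p - 0.419), 1e-3)
  expect_lt(abs(pearson_chi2(rbind(c(30, 31), c(38, 26)))$p - 0.253), 1e-3)
  expect_lt(abs(pearson_chi2(rbind(c(30, 31), c(26, 38)))$p - 0.336), 1e-3)
  flat <- pearson_chi2(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  expect_error(pearson_chi2(rbind(c(0, 0), c(5, 5))), "margin")
})

test_that("chi-square type-I error is near nominal under the null", {
  n_rep <- 2000
  hits <- withr::with_seed(17, {
    sum(replicate(n_rep, {
      g <- stats::rbinom(125, 1, 61 / 125)
      x <- stats::rbinom(125, 1, 0.5)
      tab <- table(factor(g, 0:1), factor(x, 0:1))
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) FALSE
      else pearson_chi2(tab)$p < 0.05
    }))
  })
  expect_gt(hits / n_rep, 0.03)
  expect_lt(hits / n_rep, 0.07)
})

test_that("Welch t-test reproduces the printed age comparison from summaries", {
  res <- two_sample_t(c(mean = 50.6, sd = 15.0, n = 61),
                      c(mean = 56.9, sd = 12.7, n = 64))
  expect_lt(abs(res$p - 0.013), 1e-3)
  same <- two_sample_t(c(mean = 5, sd = 2, n = 30), c(mean = 5, sd = 2, n = 30))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("summary-based and sample-based t-tests agree", {
  x <- withr::with_seed(2, stats::rnorm(40, 10, 3))
  y <- withr::with_seed(3, stats::rnorm(35, 12, 4))
  a <- two_sample_t(x, y)
  b <- two_sample_t(c(mean = mean(x), sd = sd(x), n = 40),
                    c(mean = mean(y), sd = sd(y), n = 35))
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("t-test p agrees with a permutation test on small samples", {
  x <- withr::with_seed(8, stats::rnorm(8, 0, 1))
  y <- withr::with_seed(9, stats::rnorm(8, 1.2, 1))
  t_obs <- abs(two_sample_t(x, y)$statistic)
  pooled <- c(x, y)
  perm_p <- withr::with_seed(10, {
    mean(replicate(20000, {
      ii <- sample(16, 8)
      abs(two_sample_t(pooled[ii], pooled[-ii])$statistic) >= t_obs
    }))
  })
  expect_lt(abs(two_sample_t(x, y)$p - perm_p), 0.02)
})

test_that("Mann-Whitney exact enumeration matches known cases", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$p, 0.1)
  same <- mann_whitney(c(2, 5, 9), c(2, 5, 9))
  expect_equal(same$p, 1)
  # agrees with wilcox.test's exact p when there are no ties
  x <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  y <- c(2.8, 6.0, 4.4, 7.1)
  expect_equal(mann_whitney(x, y)$p,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("normal approximation is close to exact at combined n = 12", {
  x <- withr::with_seed(4, stats::rnorm(6))
  y <- withr::with_seed(5, stats::rnorm(6, 0.5))
  exact <- mann_whitney(x, y)$p
  approx <- mann_whitney(x, y, exact_max = 0)$p
  expect_lt(abs(exact - approx), 0.01)
})

test_that("rank tests are invariant under monotone transforms", {
  x <- withr::with_seed(6, stats::rexp(10))
  y <- withr::with_seed(7, stats::rexp(12, 0.5))
  expect_equal(mann_whitney(x, y)$p, mann_whitney(log(x), log(y))$p)
  expect_equal(mann_whitney(x, y)$p, mann_whitney(exp(x), exp(y))$p)
})

test_that("Wilcoxon signed-rank enumeration matches known cases", {
  allpos <- wilcoxon_paired(c(0.5, 1.1, 2.0, 0.7, 1.4, 3.2))
  expect_true(allpos$exact)
  expect_equal(allpos$p, 0.03125)
  anti <- wilcoxon_paired(c(-1, 1))
  expect_equal(anti$p, 1)
  expect_error(wilcoxon_paired(c(0, 0, 0)), "zero")
})

test_that("signed-rank exact and approximate p agree at n = 15", {
  d <- withr::with_seed(12, stats::rnorm(15, 0.4))
  exact <- wilcoxon_paired(d)$p
  approx <- wilcoxon_paired(d, exact_max = 0)$p
  expect_lt(abs(exact - approx), 0.02)
})

test_that("ROC analysis recovers separation, AUC identities and the Youden cutoff", {
  perfect <- roc_youden(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$youden, 1.0)
  expect_equal(perfect$cutoff, 2.5)
  mixed <- roc_youden(c(2, 1, 3, 2), c(0, 1, 1, 0))
  expect_equal(mixed$auc, 0.5)
  expect_error(roc_youden(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("empirical AUC matches the brute-force pair estimator", {
  for (seed in 1:5) {
    n <- 40
    labels <- withr::with_seed(seed, stats::rbinom(n, 1, 0.5))
    if (length(unique(labels)) < 2) next
    scores <- withr::with_seed(seed + 20, round(stats::rnorm(n, labels), 1))
    r <- roc_youden(scores, labels)
    expect_equal(r$auc, brute_force_auc(scores, labels), tolerance = 1e-10)
    r_flip <- roc_youden(-scores, labels)
    expect_equal(r$auc + r_flip$auc, 1, tolerance = 1e-10)
  }
})

test_that("ICC(2,1) behaves as an absolute-agreement coefficient", {
  x <- withr::with_seed(30, stats::rnorm(50, 10, 2))
  dup <- cbind(x, x, x)
  expect_equal(icc(dup)$icc, 1.0)
  noise <- withr::with_seed(31, matrix(stats::rnorm(400), 200, 2))
  r0 <- icc(noise)$icc
  expect_lt(abs(r0), 3 / sqrt(200))
  # constant offset on one rater hurts agreement but not consistency
  shifted <- cbind(x, x + 3)
  res <- icc(shifted)
  expect_lt(res$icc, res$icc_consistency)
  expect_equal(res$icc_consistency, 1.0)
  expect_error(icc(matrix(1, 5, 2)), "constant")
})

test_that("normality gate picks the right reporting test", {
  x <- withr::with_seed(40, stats::rnorm(60))
  y <- withr::with_seed(41, stats::rnorm(60, 0.3))
  expect_identical(compare_groups(x, y)$test$test, "welch_t")
  xs <- withr::with_seed(42, stats::rlnorm(60, 0, 1.5))
  ys <- withr::with_seed(43, stats::rlnorm(60, 0.5, 1.5))
  expect_identical(compare_groups(xs, ys)$test$test, "mann_whitney")
})
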