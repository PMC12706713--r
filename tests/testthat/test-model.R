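test_that("cohort split honours the ceiling(ratio * n) convention", {
  cls <- rep(c(0, 1), c(61, 64))
  s <- split_cohort(cls, ratio = 0.7, seed = 5)
  expect_identical(s$n_train, 88L)
  expect_identical(s$n_validation, 37L)
  s10 <- split_cohort(rep(0:1, 5), ratio = 0.7, seed = 5)
  expect_identical(s10$n_train, 7L)
  s2 <- split_cohort(cls, ratio = 0.7, seed = 5)
  expect_identical(s$train, s2$train)
  # stratification keeps class balance within one patient
  tab <- table(cls, s$train)
  expect_true(all(abs(tab[, "TRUE"] - c(61, 64) * 88 / 125) <= 1))
  expect_error(split_cohort(cls, ratio = 1.2), "ratio")
})

test_that("single binary predictor recovers the log odds ratio", {
  # counts: exposed/unexposed x outcome: a=20 b=10 (x=1), c=15 d=25 (x=0)
  df <- data.frame(x = rep(c(1, 1, 0, 0), c(20, 10, 15, 25)))
  y <- rep(c(1, 0, 1, 0), c(20, 10, 15, 25))
  m <- fit_logistic(df, y, "x")
  b <- m$coefficients_table$B[m$coefficients_table$term == "x"]
  expect_equal(b, log(20 * 25 / (10 * 15)), tolerance = 1e-6)
  expect_equal(m$coefficients_table$OR, exp(m$coefficients_table$B))
  expect_equal(m$aic, stats::AIC(m$fit))
})

test_that("Wald CIs cover zero at the nominal rate under the null", {
  cover <- withr::with_seed(55, {
    mean(replicate(300, {
      df <- data.frame(x = stats::rnorm(400))
      y <- stats::rbinom(400, 1, 0.5)
      tab <- fit_logistic(df, y, "x")$coefficients_table
      row <- tab[tab$term == "x", ]
      log(row$CI_low) < 0 && 0 < log(row$CI_high)
    }))
  })
  expect_gt(cover, 0.91)
  expect_lt(cover, 0.99)
})

test_that("logistic input contracts are enforced", {
  df <- data.frame(x = rep(1, 20))
  expect_error(fit_logistic(df, rep(0:1, 10), "x"), "zero-variance")
  df2 <- data.frame(x = stats::rnorm(20))
  expect_error(fit_logistic(df2, rep(1, 20), "single class"))
  sep <- data.frame(x = c(rep(0, 10), rep(1, 10)))
  expect_warning(fit_logistic(sep, rep(0:1, each = 10), "x"), "separation")
})

test_that("AIC prefers the null model on null data", {
  wins <- withr::with_seed(60, {
    mean(replicate(100, {
      df <- data.frame(a = stats::rnorm(500), b = stats::rnorm(500),
                       c = stats::rnorm(500))
      y <- stats::rbinom(500, 1, 0.4)
      full <- fit_logistic(df, y, c("a", "b", "c"))$aic
      null <- stats::AIC(stats::glm(y ~ 1, family = stats::binomial()))
      null < full
    }))
  })
  expect_gte(wins, 0.85)
})

test_that("a single truly associated candidate is retained", {
  df <- withr::with_seed(61, data.frame(x = stats::rnorm(300)))
  y <- withr::with_seed(62, stats::rbinom(300, 1, stats::plogis(1.5 * df$x)))
  m <- select_model(df, y, "x")
  expect_identical(m$predictors, "x")
})

test_that("VIF and tolerance are reciprocal and >= 1", {
  df <- withr::with_seed(63, {
    a <- stats::rnorm(200)
    data.frame(a = a, b = a * 0.4 + stats::rnorm(200), c = stats::rnorm(200))
  })
  y <- withr::with_seed(64, stats::rbinom(200, 1, stats::plogis(df$a - df$b)))
  m <- fit_logistic(df, y, c("a", "b", "c"))
  expect_equal(m$collinearity$VIF, 1 / m$collinearity$tolerance)
  expect_true(all(m$collinearity$VIF >= 1))
})

test_that("the nomogram reproduces model probabilities exactly", {
  df <- withr::with_seed(65, data.frame(a = stats::rnorm(200, 50, 10),
                                        b = stats::runif(200),
                                        c = stats::rnorm(200)))
  y <- withr::with_seed(66, stats::rbinom(200, 1, stats::plogis(0.05 * (df$a - 50) + 2 * df$b - df$c)))
  m <- fit_logistic(df, y, c("a", "b", "c"))
  nomo <- build_nomogram(m)
  newx <- withr::with_seed(67, data.frame(a = stats::rnorm(100, 50, 10),
                                          b = stats::runif(100),
                                          c = stats::rnorm(100)))
  direct <- predict(m, newdata = newx)
  via_points <- vapply(seq_len(100), function(i) {
    total <- sum(vapply(c("a", "b", "c"), function(p) {
      nomogram_points(nomo, p, newx[[p]][i])
    }, numeric(1)))
    nomogram_probability(nomo, total)
  }, numeric(1))
  expect_lt(max(abs(direct - via_points)), 1e-6)
  # widest-effect predictor spans exactly 0-100 over its display range
  spans <- vapply(c("a", "b", "c"), function(p) {
    j <- match(p, nomo$predictors)
    abs(nomogram_points(nomo, p, nomo$hi[j]) - nomogram_points(nomo, p, nomo$lo[j]))
  }, numeric(1))
  expect_equal(max(spans), 100)
  # every point scale is nonnegative and monotone toward higher risk
  for (p in c("a", "b", "c")) {
    j <- match(p, nomo$predictors)
    grid <- seq(nomo$lo[j], nomo$hi[j], length.out = 11)
    pts <- nomogram_points(nomo, p, grid)
    expect_true(all(pts >= -1e-12))
    if (nomo$B[j] > 0) expect_true(all(diff(pts) > 0)) else expect_true(all(diff(pts) < 0))
  }
})

test_that("Hosmer-Lemeshow reproduces the printed chi-square / p pairs", {
  expect_lt(abs(stats::pchisq(12.812, 8, lower.tail = FALSE) - 0.119), 1e-3)
  expect_lt(abs(stats::pchisq(9.009, 6, lower.tail = FALSE) - 0.173), 1e-3)
})

test_that("Hosmer-Lemeshow groups by deciles of risk and validates bins", {
  probs <- withr::with_seed(70, stats::runif(500, 0.05, 0.95))
  y <- withr::with_seed(71, stats::rbinom(500, 1, probs))
  res <- hosmer_lemeshow(probs, y, groups = 10)
  expect_identical(res$df, res$groups_used - 2L)
  expect_gte(res$p, 0)
  expect_lte(res$p, 1)
  expect_error(hosmer_lemeshow(probs[1:5], y[1:5], groups = 10), "fewer")
})

test_that("calibration bootstrap reports near-unit slope for a well-specified model", {
  df <- withr::with_seed(75, data.frame(x = stats::rnorm(2000)))
  y <- withr::with_seed(76, stats::rbinom(2000, 1, stats::plogis(df$x)))
  rep <- calibration_curve(df, y, "x", B = 60, seed = 7)
  expect_equal(rep$slope_apparent, 1)
  expect_gt(rep$slope_corrected, 0.9)
  expect_lt(rep$slope_corrected, 1.1)
  expect_error(calibration_curve(df, y, "x", B = 0), "B_resamples")
})

test_that("calibration bootstrap is deterministic given the seed", {
  df <- withr::with_seed(77, data.frame(x = stats::rnorm(200)))
  y <- withr::with_seed(78, stats::rbinom(200, 1, stats::plogis(df$x)))
  a <- calibration_curve(df, y, "x", B = 25, seed = 11)
  b <- calibration_curve(df, y, "x", B = 25, seed = 11)
  expect_identical(a$slope_corrected, b$slope_corrected)
})

test_that("decision-curve identities hold", {
  probs <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  y <- c(1, 1, 0, 1, 0, 0)
  dc <- decision_curve(probs, y, thresholds = c(0.001, 0.5))
  expect_true(all(dc$treat_none == 0))
  expect_equal(dc$treat_all[1], mean(y), tolerance = 2e-3)
  expect_equal(dc$net_benefit[dc$threshold == 0.5], 1 / 6)
  expect_error(decision_curve(probs, y, numeric(0)), "empty")
  expect_error(decision_curve(probs, y, c(0, 0.5)), "inside")
})

test_that("a discriminating model beats both default policies over an interior range", {
  df <- withr::with_seed(80, data.frame(x = stats::rnorm(4000)))
  y <- withr::with_seed(81, stats::rbinom(4000, 1, stats::plogis(2 * df$x)))
  m <- fit_logistic(df, y, "x")
  dc <- decision_curve(predict(m), y, thresholds = seq(0.2, 0.8, 0.05))
  expect_true(all(dc$net_benefit >= pmax(dc$treat_all, dc$treat_none) - 1e-9))
})

test_that("training AUC on study-sized synthetic cohorts brackets the published range", {
  aucs <- vapply(1:50, function(s) {
    coh <- gen_cohort(default_config(n_patients = 125, rng_seed = s))
    rec <- coh$records
    sp <- split_cohort(rec$class, ratio = 0.7, seed = s)
    train <- rec[sp$train, ]
    cand <- c("age", "diameter_mm", "f1", "f2", "f3", "EI",
              "rADCmean", "rADCmax", "rADCmin", "rADCdif")
    scr <- suppressWarnings(univariable_screen(train, train$class, cand))
    sel <- suppressWarnings(select_model(train, train$class, scr$significant))
    roc_youden(predict(sel), train$class)$auc
  }, numeric(1))
  q <- stats::quantile(aucs, c(0.05, 0.95), names = FALSE)
  expect_gte(0.85, q[1])
  expect_lte(0.85, q[2])
})
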