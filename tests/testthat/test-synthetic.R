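test_that("configuration validation rejects bad parameters", {
  cfg <- default_config()
  cfg$prevalence_pcnsl <- 1.4
  expect_error(validate_config(cfg), "probability")
  cfg <- default_config()
  cfg$classes$GBM$age_sd <- -1
  expect_error(validate_config(cfg), "nonnegative")
  cfg <- default_config()
  cfg$classes$PCNSL$habitat_mean <- c(0.6, 0.6, 0.1)
  expect_error(validate_config(cfg), "sum to 1")
})

test_that("configuration round-trips through YAML", {
  cfg <- default_config(n_patients = 40, rng_seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(gen_cohort(cfg2), gen_cohort(cfg))
})

test_that("cohorts are deterministic given the seed", {
  a <- gen_cohort(default_config(n_patients = 50, rng_seed = 7))
  b <- gen_cohort(default_config(n_patients = 50, rng_seed = 7))
  expect_identical(a, b)
  c <- gen_cohort(default_config(n_patients = 50, rng_seed = 8))
  expect_false(identical(a$records$age, c$records$age))
})

test_that("point-mass configuration reproduces the class means exactly", {
  cfg <- default_config(n_patients = 30, rng_seed = 2)
  for (cl in names(cfg$classes)) {
    cfg$classes[[cl]]$habitat_concentration <- Inf
    cfg$classes[[cl]]$ei_logsd <- 0
    cfg$classes[[cl]]$radc_mean_logsd <- 0
    cfg$classes[[cl]]$age_sd <- 0
    cfg$classes[[cl]]$diameter_logsd <- 0
    cfg$classes[[cl]]$p_male <- 1
    cfg$classes[[cl]]$p_headache <- 0
    cfg$classes[[cl]]$p_midline <- 1
  }
  cfg$vm$discrete_noise_sd <- 0
  cfg$vm$endothelial_noise_sd <- 0
  cfg$vm$continuous_noise_sd <- 0
  coh <- gen_cohort(cfg)
  r <- coh$records
  for (cl in c("GBM", "PCNSL")) {
    s <- r[r$diagnosis == cl, ]
    pars <- cfg$classes[[cl]]
    expect_true(all(abs(s$f1 - pars$habitat_mean[1]) < 1e-12))
    expect_true(all(abs(s$EI - pars$ei_median) < 1e-12))
    expect_true(all(abs(s$rADCmean - pars$radc_mean_median) < 1e-12))
    expect_true(all(abs(s$age - pars$age_mean) < 1e-12))
    expect_true(all(abs(s$diameter_mm - pars$diameter_median) < 1e-12))
    expect_true(all(s$sex == "M"))
  }
})

test_that("generated quantities satisfy their range invariants", {
  coh <- gen_cohort(default_config(n_patients = 400, rng_seed = 13))
  r <- coh$records
  expect_true(all(abs(r$f1 + r$f2 + r$f3 - 1) < 1e-12))
  expect_true(all(r$EI >= 1))
  expect_true(all(r$discrete_vm_density >= 0))
  expect_true(all(r$endothelial_density >= 0))
  expect_true(all(r$continuous_vm_prob >= 0 & r$continuous_vm_prob <= 1))
  expect_true(all(r$rADCmin <= r$rADCmean & r$rADCmean <= r$rADCmax))
  expect_equal(r$rADCdif, r$rADCmax - r$rADCmin)
})

test_that("per-class sample moments match the configured values at n = 500", {
  coh <- gen_cohort(default_config(n_patients = 500, rng_seed = 31))
  r <- coh$records
  cfg <- default_config()
  for (cl in c("GBM", "PCNSL")) {
    s <- r[r$diagnosis == cl, ]
    n <- nrow(s)
    pars <- cfg$classes[[cl]]
    # means within 3 standard errors
    expect_lt(abs(mean(s$f1) - pars$habitat_mean[1]), 3 * sd(s$f1) / sqrt(n))
    expect_lt(abs(mean(s$f2) - pars$habitat_mean[2]), 3 * sd(s$f2) / sqrt(n))
    # medians within 3 asymptotic SEs (1.2533 * sd / sqrt(n) scale)
    expect_lt(abs(median(s$EI) - pars$ei_median),
              3 * 1.2533 * sd(s$EI) / sqrt(n))
    expect_lt(abs(median(s$rADCmean) - pars$radc_mean_median),
              3 * 1.2533 * sd(s$rADCmean) / sqrt(n))
  }
})

test_that("phantom construction realizes fractions, EI and layout exactly", {
  tr <- make_truth(f = c(0.5, 0.5, 0), ei = 2, radc = 1.2)
  ph <- render_phantom(tr, seed = 5)
  n_tumor <- sum(ph$masks$tumor$values)
  labs <- ph$habitat_truth$values[ph$masks$tumor$values == 1]
  expect_equal(sum(labs == 1), n_tumor / 2)
  expect_equal(sum(labs == 2), n_tumor / 2)
  expect_equal(sum(ph$masks$edema$values), n_tumor)
  # noiseless: exactly half the tumor voxels carry the habitat-1 signature
  t1_tumor <- ph$t1ce$values[ph$masks$tumor$values == 1]
  expect_equal(sum(t1_tumor == 180), n_tumor / 2)

  single <- render_phantom(make_truth(f = c(1, 0, 0), ei = 1.3), seed = 5)
  labs1 <- single$habitat_truth$values[single$masks$tumor$values == 1]
  expect_true(all(labs1 == 1))
})

test_that("phantoms reject infeasible sizing", {
  tr <- make_truth(ei = 50)
  expect_error(render_phantom(tr, shape = c(16, 16, 8)), "sizing")
})

test_that("speckled and shell layouts share composition but differ in geometry", {
  tr <- make_truth()
  a <- render_phantom(tr, seed = 9, layout = "shells")
  b <- render_phantom(tr, seed = 9, layout = "speckled")
  expect_identical(a$realized$counts, b$realized$counts)
  expect_false(identical(a$habitat_truth$values, b$habitat_truth$values))
})

test_that("the full pipeline recovers noiseless phantom ground truth exactly", {
  coh <- gen_cohort(default_config(n_patients = 200, rng_seed = 17))
  ok <- which(apply(coh$truth[, c("f1", "f2", "f3")], 1, min) > 0.02)
  picks <- ok[seq_len(20)]
  for (i in picks) {
    tr <- coh$truth[i, ]
    ph <- render_phantom(tr, seed = i)
    res <- process_patient(ph$t1ce, ph$adc, ph$masks, seed = i + 1)
    expect_equal(unname(res$fractions), ph$realized$fractions, tolerance = 1e-12)
    expect_equal(unname(res$metrics["EI"]), ph$realized$ei, tolerance = 1e-12)
    expect_equal(unname(res$metrics["rADCmean"]), ph$realized$radc_mean,
                 tolerance = 1e-9)
    expect_equal(unname(res$metrics["rADCmax"]), ph$realized$radc_max,
                 tolerance = 1e-9)
    expect_equal(unname(res$metrics["rADCmin"]), ph$realized$radc_min,
                 tolerance = 1e-9)
    # realized fractions are within one voxel of the latent targets
    f_target <- unlist(tr[c("f1", "f2", "f3")])
    expect_true(all(abs(ph$realized$counts - f_target * ph$realized$n_tumor) <= 1))
  }
})

test_that("noiseless clustering reproduces the generative subregions voxelwise", {
  tr <- make_truth()
  ph <- render_phantom(tr, seed = 23)
  res <- process_patient(ph$t1ce, ph$adc, ph$masks, seed = 24)
  truth_labels <- ph$habitat_truth$values[ph$masks$tumor$values == 1]
  expect_identical(res$habitat_map$labels, as.integer(truth_labels))
})

test_that("VM counting sheets are Poisson at the configured density", {
  tr <- make_truth()
  tr$discrete_vm_density <- 0
  sheet0 <- gen_vm_counts(tr, seed = 1)
  expect_true(all(sheet0$discrete_vm == 0))
  tr$discrete_vm_density <- 8
  many <- gen_vm_counts(tr, seed = 2, n_boxes = 10000, n_observers = 1)
  est <- mean(many$discrete_vm) / 0.275
  se <- sqrt(8 / 0.275 / 10000)  # Poisson SE of the density estimate
  expect_lt(abs(est - 8), 4 * se)
  expect_identical(gen_vm_counts(tr, seed = 3), gen_vm_counts(tr, seed = 3))
})
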