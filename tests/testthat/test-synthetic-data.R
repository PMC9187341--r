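test_that("feature and cohort configuration are validated", {
  expect_error(feature_spec("f", "unimodal", mu1 = 2, mu2 = 3), "mu1 == mu2")
  expect_error(feature_spec("f", "tumor_bimodal", mu1 = 2, mu2 = 8, pi1 = 0),
               "pi1")
  expect_error(feature_spec("f", "tumor_bimodal", mu1 = 8, mu2 = 2), "mu1")
  expect_error(feature_spec("f", "unimodal", mu1 = 2, sigma1 = -1),
               "positive")
  specs <- spec_batch(2, "f", archetype = "unimodal", mu1 = 5)
  expect_error(cohort_config(10, 20, specs), "n_control")
  expect_error(cohort_config(20, 10, specs, hazard_ratio = 0), "positive")
  expect_error(cohort_config(20, 10, specs, censor_rate = 1), "censor_rate")
  expect_error(cohort_config(20, 10, specs,
                             drug_panel = data.frame(drug_id = "d",
                                                     target_corr = 1.5)),
               "target_corr")
})

test_that("archetypes generate the planted structure", {
  specs <- list(
    feature_spec("uni", "unimodal", mu1 = 5),
    feature_spec("tb", "tumor_bimodal", mu1 = 2, mu2 = 8, pi1 = 0.5),
    feature_spec("low", "low_expressed", mu1 = 1, zero_frac = 0.97))
  cfg <- cohort_config(400, 100, specs, seed = 71)
  sim <- generate_cohort(cfg)

  # dimension contract
  expect_identical(dim(sim$tumor$values), c(3L, 400L))
  expect_identical(dim(sim$control$values), c(3L, 100L))
  expect_identical(sim$truth$features$archetype,
                   c("unimodal", "tumor_bimodal", "low_expressed"))

  # law of large numbers on planted components
  tb <- sim$tumor$values["tb", ]
  mem <- sim$truth$membership_tumor["tb", ]
  expect_equal(mean(tb[mem == 1]), 2, tolerance = 0.25)
  expect_equal(mean(tb[mem == 2]), 8, tolerance = 0.25)
  expect_equal(mean(sim$control$values["tb", ]), 2, tolerance = 0.25)
  expect_equal(mean(sim$tumor$values["uni", ]), 5, tolerance = 0.25)

  # low-expressed features are almost all zero
  expect_gte(mean(sim$tumor$values["low", ] == 0), 0.9)
})

test_that("the generator is fully determined by its seed", {
  specs <- discrimination_specs()
  s1 <- generate_cohort(cohort_config(50, 20, specs, seed = 7))
  s2 <- generate_cohort(cohort_config(50, 20, specs, seed = 7))
  expect_identical(s1$tumor$values, s2$tumor$values)
  expect_identical(s1$control$values, s2$control$values)
  expect_identical(s1$truth$subgroup, s2$truth$subgroup)
  s3 <- generate_cohort(cohort_config(50, 20, specs, seed = 8))
  expect_false(identical(s1$tumor$values, s3$tumor$values))
})

test_that("planted mixtures are recovered by the mixture fitter", {
  cfg <- cohort_config(400, 100,
                       spec_batch(1, "tb", archetype = "tumor_bimodal",
                                  mu1 = 2, mu2 = 8, pi1 = 0.5),
                       seed = 72)
  sim <- generate_cohort(cfg)
  f <- fit_em(sim$tumor$values[1, ], 2)
  expect_equal(f$mu[1], 2, tolerance = 0.25)
  expect_equal(f$mu[2], 8, tolerance = 0.25)
  expect_equal(f$pi[1], 0.5, tolerance = 0.07)
})

test_that("clinical tables honor censoring and hazard configuration", {
  subgroup <- factor(rep(c("low", "high"), 100), levels = c("low", "high"))
  names(subgroup) <- sprintf("T%04d", 1:200)
  truth <- list(subgroup = subgroup)

  cfg0 <- cohort_config(200, 50, list(), censor_rate = 0, seed = 73)
  clin0 <- generate_clinical(truth, cfg0)
  expect_true(all(clin0$event == 1L))
  expect_identical(clin0$sample_id, names(subgroup))

  cfg2 <- cohort_config(200, 50, list(), censor_rate = 0.3, seed = 73)
  clin2 <- generate_clinical(truth, cfg2)
  expect_equal(mean(clin2$event == 0L), 0.3, tolerance = 0.12)
  expect_true(all(clin2$stage %in% c("I", "II", "III", "IV")))
  expect_true(all(clin2$sex %in% c("F", "M")))

  # same seed, same table
  expect_identical(clin2, generate_clinical(truth, cfg2))
})

test_that("drug panels hit their target correlations", {
  panel <- data.frame(drug_id = c("exact", "mid", "null"),
                      target_corr = c(-1, -0.5, 0))
  # |r| = 1 exactly when the noise weight is zero
  cfg <- cohort_config(10, 5, list(), drug_panel = panel, seed = 74)
  p <- generate_drug_panel(cfg, 13)
  expect_identical(dim(p$ic50), c(13L, 3L))
  expect_equal(cor(p$expression, log(p$ic50[, "exact"])), -1,
               tolerance = 1e-12)

  # the mean empirical correlation over many panels is close to target
  rs <- vapply(1:100, function(s) {
    pp <- generate_drug_panel(cohort_config(10, 5, list(),
                                            drug_panel = panel,
                                            seed = 100 + s), 13)
    c(cor(pp$expression, log(pp$ic50[, "mid"])),
      cor(pp$expression, log(pp$ic50[, "null"])))
  }, numeric(2))
  expect_equal(mean(rs[1, ]), -0.5, tolerance = 0.05)
  expect_lt(abs(mean(rs[2, ])), 0.05)

  expect_error(generate_drug_panel(cfg, 2), "at least 3")
  expect_error(generate_drug_panel(cohort_config(10, 5, list(), seed = 1),
                                   13), "no drug panel")
})
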