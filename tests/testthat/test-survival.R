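test_that("hierarchical stratification separates planted blobs exactly", {
  set.seed(51)
  lowv <- matrix(rnorm(3 * 50, 0, 0.5), 3)
  highv <- matrix(rnorm(3 * 50, 8, 0.5), 3)
  vals <- cbind(lowv, highv)
  rownames(vals) <- paste0("miR", 1:3)
  colnames(vals) <- sprintf("s%03d", 1:100)
  m <- expression_matrix(vals, "tumor", "log2")
  lab <- stratify_hierarchical(m, paste0("miR", 1:3))
  expect_identical(as.character(lab),
                   rep(c("low", "high"), each = 50))

  # invariant to sample order (same partition)
  perm <- sample(100)
  m2 <- expression_matrix(vals[, perm], "tumor", "log2")
  lab2 <- stratify_hierarchical(m2, paste0("miR", 1:3))
  expect_identical(lab2[names(lab)], lab)

  # two samples: one per group
  tiny <- expression_matrix(vals[, 1:2], "tumor", "log2")
  expect_identical(sort(as.character(stratify_hierarchical(tiny, "miR1"))),
                   c("high", "low"))
  expect_error(stratify_hierarchical(expression_matrix(
    vals[, 1, drop = FALSE], "tumor", "log2"), "miR1"), "at least 2")
})

test_that("mixture-assignment stratification follows the planted subgroup", {
  cfg <- cohort_config(200, 50, spec_batch(3, "mod",
                                           archetype = "tumor_bimodal",
                                           mu1 = 2, mu2 = 8, linked = TRUE),
                       seed = 52)
  sim <- generate_cohort(cfg)
  feats <- rownames(sim$tumor$values)
  lab_h <- stratify_hierarchical(sim$tumor, feats)
  lab_m <- stratify_hierarchical(sim$tumor, feats, method = "mixture")
  truthg <- sim$truth$subgroup
  expect_gte(mean(lab_h == truthg), 0.99)
  expect_gte(mean(lab_m == truthg), 0.99)
})

test_that("the proportional-hazards fit recovers a planted hazard ratio", {
  cfg <- cohort_config(500, 50, list(), hazard_ratio = 2,
                       censor_rate = 0.2, seed = 53)
  subgroup <- factor(rep(c("low", "high"), each = 250),
                     levels = c("low", "high"))
  names(subgroup) <- sprintf("T%04d", 1:500)
  clin <- generate_clinical(list(subgroup = subgroup), cfg)
  res <- fit_cox(subgroup, clin)
  expect_gt(res$hr, 1.6)
  expect_lt(res$hr, 2.5)
  expect_lt(res$wald_p, 0.05)
  expect_true(res$ci_low <= res$hr && res$hr <= res$ci_high)
  expect_identical(res$n_per_group, c(250L, 250L))
  expect_true(all(c("low", "high") %in% res$median_survival$group))

  # relabeling symmetry: HR inverts exactly, the Wald p is unchanged
  flipped <- factor(ifelse(subgroup == "high", "low", "high"),
                    levels = c("low", "high"))
  names(flipped) <- names(subgroup)
  res2 <- fit_cox(flipped, clin)
  expect_equal(res2$hr, 1 / res$hr, tolerance = 1e-8)
  expect_equal(res2$wald_p, res$wald_p, tolerance = 1e-8)
})

test_that("groups without events are rejected", {
  clin <- data.frame(sample_id = paste0("s", 1:20),
                     time_days = rexp(20, 1 / 500),
                     event = rep(c(1L, 0L), each = 10))
  grp <- factor(rep(c("low", "high"), each = 10), levels = c("low", "high"))
  names(grp) <- clin$sample_id
  expect_error(fit_cox(grp, clin), "no observed events")
})

test_that("stage association matches hand chi-square values", {
  g <- factor(rep(c("low", "high"), each = 20))
  names(g) <- paste0("s", 1:40)

  even <- rep(rep(c("I", "II"), each = 10), 2)
  res <- stage_association(g, even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  split <- c(rep("I", 20), rep("II", 20))
  res2 <- stage_association(g, split)
  expect_equal(res2$statistic, 40)   # 2x2, no continuity correction
  expect_identical(res2$low_expected_cells, 0L)
})

test_that("a stage-coupled generator yields a detectable association", {
  cfg <- cohort_config(400, 50, list(), hazard_ratio = 1, seed = 54,
                       stage_shift = 1.5)
  set.seed(54)
  subgroup <- factor(sample(c("low", "high"), 400, TRUE),
                     levels = c("low", "high"))
  names(subgroup) <- sprintf("T%04d", 1:400)
  clin <- generate_clinical(list(subgroup = subgroup), cfg)
  res <- stage_association(subgroup, clin$stage)
  expect_lt(res$p_value, 0.05)

  # and the default generator leaves stage independent of the subgroup
  cfg0 <- cohort_config(400, 50, list(), seed = 55)
  clin0 <- generate_clinical(list(subgroup = subgroup), cfg0)
  res0 <- stage_association(subgroup, clin0$stage)
  expect_gt(res0$p_value, 0.001)
})
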