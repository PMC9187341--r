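test_that("bimodality index matches hand arithmetic", {
  expect_equal(bimodality_index(0.5, 0.5, 0, 2, 1, 1), 1.0,
               tolerance = 1e-12)
  expect_equal(bimodality_index(0.2, 0.8, 0, 3, 1, 1), 1.2,
               tolerance = 1e-12)
  expect_identical(bimodality_index(0.3, 0.7, 4, 4, 1, 2), 0)
  expect_error(bimodality_index(0.5, 0.6, 0, 2, 1, 1), "sum to 1")
  expect_error(bimodality_index(0.5, 0.5, 3, 2, 1, 1), "ordered")
  expect_error(bimodality_index(0.5, 0.5, 0, 2, 0, 1), "positive")
})

test_that("the index is invariant to shifting and positive rescaling", {
  set.seed(31)
  x <- c(rnorm(100, 1, 0.5), rnorm(100, 4, 0.8))
  bi_of <- function(v) {
    km <- kmeans_recluster(v)
    bimodality_index(km$pi[1], km$pi[2], km$mu[1], km$mu[2],
                     km$sigma[1], km$sigma[2])
  }
  b0 <- bi_of(x)
  expect_equal(bi_of(x + 7.3), b0, tolerance = 1e-8)
  expect_equal(bi_of(x * 2.6), b0, tolerance = 1e-8)
})

test_that("control penalties follow the inverse-distance ledger", {
  # mean distances sum to 10, proportion distances to 0.05
  tumor <- fake_fit2(mu = c(0, 5), pi = c(0.500, 0.500))
  control <- fake_fit2(mu = c(4, 11), pi = c(0.525, 0.475))
  pen <- penalized_bi(1.92, tumor, control)
  expect_equal(pen$bi_mu_penalty, 1.82, tolerance = 1e-12)
  expect_equal(pen$bi_pi_penalty, 1.92 - 20, tolerance = 1e-12)
  expect_equal(pen$bi_final, 1.82, tolerance = 1e-12)

  # identical tumor/control parameters: fully penalized
  same <- penalized_bi(2.5, tumor, tumor)
  expect_identical(same$bi_final, 0)

  # penalty vanishes as the control drifts far away
  far <- penalized_bi(1.92, tumor, fake_fit2(mu = c(500, 505)))
  expect_equal(far$bi_final, 1.92 - 1 / 1000, tolerance = 1e-12)

  # monotone in the mean-distance sum, tumor held fixed
  shifts <- c(0.5, 1, 2, 5, 50)
  pens <- vapply(shifts, function(s)
    penalized_bi(2, tumor, fake_fit2(mu = c(0 + s, 5 + s)))$bi_mu_penalty,
    numeric(1))
  expect_true(all(diff(pens) > 0))
})

test_that("CM keeps tumor-specific bimodality and suppresses shared", {
  set.seed(32)
  tumor <- c(rnorm(250, 2, 1), rnorm(250, 8, 1))
  # control unimodal: unpenalized call above threshold
  cc <- cm_score(tumor, rnorm(500, 2, 1))
  expect_false(cc$penalized)
  expect_identical(cc$tumor_verdict, "bimodal")
  expect_gt(cc$bi_final, 1.4)

  # tumor unimodal: zero score under both variants
  expect_identical(cm_score(rnorm(300, 5, 1), rnorm(300, 5, 1))$bi_final, 0)
  expect_identical(mm_score(rnorm(300, 5, 1))$bi_final, 0)

  # tumor and control from the same mixture: near-complete suppression
  suppressed <- vapply(1:60, function(s) {
    set.seed(400 + s)
    tu <- c(rnorm(250, 2, 1), rnorm(250, 8, 1))
    co <- c(rnorm(250, 2, 1), rnorm(250, 8, 1))
    cm_score(tu, co)$bi_final
  }, numeric(1))
  expect_gte(mean(suppressed < 0.3), 0.95)
})

test_that("the penalty never raises a score above the uncontrolled one", {
  set.seed(33)
  for (i in 1:10) {
    tu <- c(rnorm(80, 2, 1), rnorm(80, 6 + runif(1, 0, 3), 1))
    co <- c(rnorm(40, 2, 1), rnorm(40, 6, 1))
    expect_lte(cm_score(tu, co)$bi_final, mm_score(tu)$bi_final + 1e-12)
  }
})

test_that("feature ranking sorts, counts thresholds and breaks ties", {
  calls <- data.frame(feature_id = c("c", "a", "b"),
                      bi_final = c(0.5, 2.2, 1.92))
  r <- rank_features(calls)
  expect_identical(r$feature_id, c("a", "b", "c"))
  expect_identical(unname(attr(r, "threshold_counts")["BI>1.4"]), 2L)

  ties <- data.frame(feature_id = c("z", "m", "a"), bi_final = rep(1, 3))
  expect_identical(rank_features(ties)$feature_id, c("a", "m", "z"))

  empty <- rank_features(data.frame(feature_id = character(0),
                                    bi_final = numeric(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("false-positive simulation is calibrated and monotone", {
  # an infinite threshold can never be exceeded
  expect_identical(simulate_fpr(50, 20, Inf, seed = 1), 0)

  # non-increasing in the threshold (same seed, same simulated features)
  f_low <- simulate_fpr(50, 300, 1.2, seed = 5)
  f_high <- simulate_fpr(50, 300, 1.6, seed = 5)
  expect_lte(f_high, f_low)

  # non-increasing in the sample size
  expect_lte(simulate_fpr(200, 300, 1.4, seed = 6),
             simulate_fpr(50, 300, 1.4, seed = 6) + 0.005)

  # power companion: a well-separated planted mixture is almost always found
  set.seed(34)
  found <- vapply(1:100, function(i) {
    x <- c(rnorm(25, 2, 1), rnorm(25, 8, 1))
    mm_score(x)$bi_final > 1.4
  }, logical(1))
  expect_gte(mean(found), 0.95)
})
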