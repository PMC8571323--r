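small_spec <- function(seed = 1, n_keep = 2000, n_adapt = 500, n_burnin = 500) {
  bayes_model_spec(n_keep = n_keep, n_adapt = n_adapt, n_burnin = n_burnin, seed = seed)
}

test_that("the saturated subtype design has one intercept and one treatment effect per subtype", {
  cohort <- generate_trial_cohort(cohort_sim_config(seed = 1))
  design <- build_subtype_design(cohort, threshold = 10.5)
  expect_equal(ncol(design$x), 8)
  expect_equal(sum(startsWith(colnames(design$x), "alpha:")), 4)
  expect_equal(sum(startsWith(colnames(design$x), "gamma:")), 4)
  # each row activates exactly its subtype's alpha, plus gamma iff experimental
  i <- which(design$subtype == "HRneg/Low" & design$trt == 1)[1]
  active <- colnames(design$x)[design$x[i, ] != 0]
  expect_setequal(active, c("alpha:HRneg/Low", "gamma:HRneg/Low"))
  j <- which(design$trt == 0)[1]
  expect_equal(sum(design$x[j, ] != 0), 1)
})

test_that("an all-HR-positive cohort leaves the HR-negative subtypes empty with a warning", {
  cohort <- generate_trial_cohort(cohort_sim_config(hr_neg_fraction = 0, seed = 2))
  expect_warning(design <- build_subtype_design(cohort, 10.5), "empty subtype")
  expect_equal(sum(table(design$subtype) > 0), 2)
})

test_that("with zero data the sampler reproduces the N(0,1) prior", {
  x <- matrix(numeric(0), nrow = 0, ncol = 3,
              dimnames = list(NULL, c("b1", "b2", "b3")))
  draws <- sample_posterior(bayes_model_spec(seed = 5), x, numeric(0))
  expect_equal(nrow(draws), 10000)
  for (j in 1:3) {
    expect_lt(abs(mean(draws[, j])), 0.05)
    expect_lt(abs(sd(draws[, j]) - 1), 0.05)
  }
})

test_that("a one-coefficient posterior matches deterministic quadrature", {
  withr::with_seed(13, {
    y <- rbinom(50, 1, 0.65)
  })
  x <- matrix(1, 50, 1, dimnames = list(NULL, "alpha"))
  draws <- sample_posterior(bayes_model_spec(seed = 3), x, y)
  grid <- seq(-6, 6, length.out = 4001)
  logpost <- -0.5 * grid^2 + sum(y) * grid - 50 * log1p(exp(grid))
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  mean_q <- sum(w * grid)
  sd_q <- sqrt(sum(w * (grid - mean_q)^2))
  expect_lt(abs(mean(draws[, 1]) - mean_q), 0.02)
  expect_lt(abs(sd(draws[, 1]) - sd_q), 0.02)
})

test_that("the sampler is deterministic given its seed", {
  cohort <- generate_trial_cohort(cohort_sim_config(seed = 4))
  design <- build_subtype_design(cohort, 10.5)
  d1 <- sample_posterior(small_spec(seed = 11), design)
  d2 <- sample_posterior(small_spec(seed = 11), design)
  expect_identical(unclass(d1)[, ], unclass(d2)[, ])
  d3 <- sample_posterior(small_spec(seed = 12), design)
  expect_false(identical(d1[1, ], d3[1, ]))
})

test_that("post-adaptation acceptance rates sit near the tuned band", {
  cohort <- generate_trial_cohort(cohort_sim_config(seed = 6))
  design <- build_subtype_design(cohort, 10.5)
  draws <- sample_posterior(small_spec(seed = 7, n_keep = 4000), design)
  acc <- attr(draws, "acceptance")
  expect_true(all(acc > 0.2 & acc < 0.7))
})

test_that("split-half coefficient means agree within Monte-Carlo error", {
  cohort <- generate_trial_cohort(cohort_sim_config(seed = 8))
  design <- build_subtype_design(cohort, 10.5)
  draws <- sample_posterior(bayes_model_spec(seed = 9), design)
  half <- nrow(draws) / 2
  batch_mcse <- function(v, n_batch = 20) {
    bm <- colMeans(matrix(v, ncol = n_batch))
    sd(bm) / sqrt(n_batch)
  }
  for (j in seq_len(ncol(draws))) {
    a <- draws[seq_len(half), j]
    b <- draws[half + seq_len(half), j]
    # batch-means MCSE accounts for chain autocorrelation; the 4-SE bound
    # keeps the familywise false-alarm rate across 8 coefficients below 1%
    mcse <- sqrt(batch_mcse(a)^2 + batch_mcse(b)^2)
    expect_lt(abs(mean(a) - mean(b)), 4 * mcse)
  }
})

test_that("degenerate draws at zero give probability one half exactly", {
  cohort <- generate_trial_cohort(cohort_sim_config(seed = 10))
  design <- build_subtype_design(cohort, 10.5)
  zero <- matrix(0, 100, ncol(design$x), dimnames = list(NULL, colnames(design$x)))
  class(zero) <- c("posterior_draws", "matrix")
  est <- estimate_pcr(zero, design, "TDM1P", "all")
  expect_equal(est$mean_prob, 0.5)
  expect_equal(unname(est$pi95), c(0.5, 0.5))
})

test_that("probability estimates are invariant to subtype relabeling in the mixture", {
  cohort <- generate_trial_cohort(cohort_sim_config(seed = 12))
  design <- build_subtype_design(cohort, 10.5)
  draws <- sample_posterior(small_spec(seed = 14), design)
  est <- estimate_pcr(draws, design, "TDM1P", "High")
  # recompute with the subtype mixture assembled in reversed order
  w <- est$weights
  trt <- 1
  probs <- numeric(nrow(draws))
  for (s in rev(design$subtype_levels)) {
    if (w[s] == 0) next
    eta <- draws[, paste0("alpha:", s)] + draws[, paste0("gamma:", s)] * trt
    probs <- probs + as.numeric(w[s]) * plogis(eta)
  }
  expect_equal(est$mean_prob, mean(probs), tolerance = 1e-12)
  expect_error(estimate_pcr(draws, design, "TDM1P", "nonexistent"), "unknown subset")
})

test_that("with a well-populated design, posterior modes track empirical cell logits", {
  cfg <- cohort_sim_config(n_per_arm = c(TDM1P = 400, TH = 400, THP = 0),
                           biomarker_mean = c(TDM1P = 10, TH = 10, THP = 10),
                           beta0 = 0, beta_arm = 0.8, beta_marker = 0,
                           beta_interaction = 0, beta_hr = -0.5, seed = 15)
  cohort <- generate_trial_cohort(cfg)
  design <- build_subtype_design(cohort, 10)
  draws <- sample_posterior(small_spec(seed = 16, n_keep = 4000), design)
  for (s in design$subtype_levels) {
    for (trt_val in c(0, 1)) {
      rows <- design$subtype == s & design$trt == trt_val
      if (sum(rows) < 40) next
      emp <- mean(design$y[rows])
      if (emp %in% c(0, 1)) next
      eta <- draws[, paste0("alpha:", s)] + draws[, paste0("gamma:", s)] * trt_val
      post_prob <- mean(plogis(eta))
      # prior N(0,1) shrinks mildly; cells of 40+ should sit close to empirical
      expect_lt(abs(post_prob - emp), 0.08)
    }
  }
})
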