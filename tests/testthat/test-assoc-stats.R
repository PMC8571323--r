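test_that("logistic MLE reproduces closed forms on saturated designs", {
  # intercept-only: 3 of 10 positive
  y <- c(rep(1, 3), rep(0, 7))
  fit <- fit_logistic(matrix(1, 10, 1), y)
  expect_equal(unname(fit$coefficients[1]), log(3 / 7), tolerance = 1e-8)
  # 2x2 saturated design: coefficient equals the log odds ratio of the table
  g <- rep(c(0, 1), c(12, 14))
  y2 <- c(rep(1, 3), rep(0, 9), rep(1, 9), rep(0, 5))
  fit2 <- fit_logistic(cbind(1, g), y2)
  lor <- log((9 / 5) / (3 / 9))
  expect_equal(unname(fit2$coefficients[2]), lor, tolerance = 1e-8)
})

test_that("logistic log-likelihood matches a nested grid-search oracle", {
  withr::with_seed(41, {
    for (i in 1:5) {
      x <- cbind(1, rnorm(60))
      y <- rbinom(60, 1, plogis(0.3 * x[, 2]))
      fit <- fit_logistic(x, y)
      expect_equal(fit$loglik, grid_max_loglik(x, y), tolerance = 1e-4)
    }
  })
})

test_that("degenerate logistic inputs are rejected or diagnosed", {
  expect_error(fit_logistic(matrix(1, 5, 1), rep(1, 5)), "constant")
  expect_error(fit_logistic(cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8)), c(0, 1, 0, 1)),
               "rank deficient")
  # complete separation: flagged, not an error
  sep <- fit_logistic(cbind(1, c(-2, -1, 1, 2, -1.5, 1.5)), c(0, 0, 1, 1, 0, 1))
  expect_false(sep$converged)
})

test_that("LR test follows the chi-square(1) reference distribution", {
  y <- rep(c(0, 1), c(6, 6))
  x <- cbind(1, c(rnorm(6, 0), rnorm(6, 0.5)))
  full <- fit_logistic(x, y)
  red <- fit_logistic(x[, 1, drop = FALSE], y)
  same <- lr_test(full, full)
  expect_equal(same$lr_stat, 0)
  expect_equal(same$p, 1)
  lrt <- lr_test(full, red)
  # independent chi-square(1) survival identity: S(x) = 2 * (1 - Phi(sqrt(x)))
  expect_equal(lrt$p, 2 * (1 - pnorm(sqrt(lrt$lr_stat))), tolerance = 1e-12)
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  expect_error(lr_test(red, full), "one term|nested")
})

test_that("per-arm qualification is null-calibrated when the biomarker is inert", {
  ps <- vapply(1:200, function(s) {
    cohort <- generate_trial_cohort(null_trial_config(s))
    qualify_biomarker(cohort, "RAB5A", "TDM1P")$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})

test_that("qualification rejects degenerate subsets and constant biomarkers", {
  cohort <- generate_trial_cohort(cohort_sim_config(seed = 2))
  tiny <- cohort[cohort$arm == "TDM1P", ][1:8, ]
  expect_error(qualify_biomarker(tiny, "RAB5A", "TDM1P"), "fewer than 10")
  const <- cohort
  const$RAB5A <- 10
  expect_error(qualify_biomarker(const, "RAB5A", "TDM1P"), "constant")
})

test_that("interaction test has power under a strong generating interaction", {
  hits <- vapply(1:100, function(s) {
    cfg <- cohort_sim_config(n_per_arm = c(TDM1P = 500, TH = 500, THP = 0),
                             biomarker_mean = c(TDM1P = 10.35, TH = 11, THP = 10.5),
                             beta0 = -1.05, beta_arm = -9, beta_marker = 0,
                             beta_interaction = 1.0, beta_hr = 0.4, seed = s)
    interaction_test(generate_trial_cohort(cfg), "RAB5A")$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("interaction test errors without both arms and reports per-SD effects", {
  cohort <- generate_trial_cohort(cohort_sim_config(seed = 3))
  one_arm <- cohort[cohort$arm == "TDM1P", ]
  expect_error(interaction_test(one_arm, "RAB5A"), "both arms")
  res <- interaction_test(cohort, "RAB5A")
  expect_equal(res$odds_ratio_per_sd, exp(res$coef), tolerance = 1e-12)
  expect_lte(res$ci95[1], res$ci95[2])
})

test_that("LR statistic is invariant to affine rescaling of the biomarker", {
  cohort <- generate_trial_cohort(cohort_sim_config(seed = 5))
  base <- qualify_biomarker(cohort, "RAB5A", "TDM1P")
  scaled <- cohort
  scaled$RAB5A <- 5 * scaled$RAB5A - 30
  res <- qualify_biomarker(scaled, "RAB5A", "TDM1P")
  expect_equal(res$lr_stat, base$lr_stat, tolerance = 1e-7)
  expect_equal(res$coef, base$coef, tolerance = 1e-7)
  inter <- interaction_test(cohort, "RAB5A")
  inter_s <- interaction_test(scaled, "RAB5A")
  expect_equal(inter_s$lr_stat, inter$lr_stat, tolerance = 1e-7)
})

test_that("association table enumerates marker-by-model rows consistently", {
  cohort <- generate_trial_cohort(cohort_sim_config(seed = 4))
  tab <- association_table(cohort, c("RAB4A", "RAB5A", "RAB11A"))
  expect_equal(nrow(tab), 9)
  expect_equal(tab$sign, sign(tab$coef))
  expect_equal(tab$neg_log10_p, -log10(tab$p), tolerance = 1e-12)
  row <- tab[tab$marker == "RAB5A" & tab$model == "TDM1P", ]
  direct <- qualify_biomarker(cohort, "RAB5A", "TDM1P")
  expect_equal(row$p, direct$p)
  expect_equal(row$odds_ratio_per_sd, direct$odds_ratio_per_sd)
})

test_that("Fisher exact test reproduces hand-enumerated hypergeometric values", {
  # margins all 5: only a=0 and a=5 are as or less probable; each 1/252
  expect_equal(fisher_exact_2x2(0, 5, 5, 0), 1 / 126, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1)
  expect_equal(round(fisher_exact_2x2(12, 28, 5, 7), 2), 0.50)
  expect_lt(abs(fisher_exact_2x2(12, 28, 5, 7) - 0.49), 0.01)
})

test_that("Fisher exact test is symmetric under row and column swaps", {
  p <- fisher_exact_2x2(3, 9, 7, 2)
  expect_equal(fisher_exact_2x2(7, 2, 3, 9), p)
  expect_equal(fisher_exact_2x2(9, 3, 2, 7), p)
  expect_warning(p0 <- fisher_exact_2x2(0, 0, 3, 4), "margin")
  expect_equal(p0, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("Mann-Whitney agrees with small-sample enumeration and handles ties", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(res$U), 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  same <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p, 1)
})

test_that("exact Mann-Whitney p matches a full-enumeration oracle at n = 8 and 11", {
  withr::with_seed(61, {
    x <- rnorm(8)
    y <- rnorm(11, 0.4)
  })
  res <- mann_whitney(x, y)
  u_obs <- u_statistic(x, y)
  expect_equal(unname(res$U), u_obs)
  # enumerate all C(19, 8) label assignments of the pooled values
  pool <- c(x, y)
  combos <- combn(19, 8)
  us <- apply(combos, 2, function(idx) u_statistic(pool[idx], pool[-idx]))
  mu <- 8 * 11 / 2
  p_enum <- if (u_obs > mu) {
    2 * mean(us >= u_obs)
  } else {
    2 * mean(us <= u_obs)
  }
  expect_equal(res$p, min(p_enum, 1), tolerance = 1e-12)
})
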