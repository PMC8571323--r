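test_that("balanced splits halve every arm-by-pCR stratum", {
  cohort <- generate_trial_cohort(cohort_sim_config(
    n_per_arm = c(TDM1P = 40, TH = 40, THP = 0),
    beta0 = 0, beta_arm = 0, beta_marker = 0, beta_interaction = 0,
    beta_hr = 0, seed = 19))
  sp <- split_balanced(cohort, seed = 1)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(cohort))
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  strata <- table(cohort$arm, cohort$pcr)
  tr <- table(factor(sp$train$arm, levels = rownames(strata)), sp$train$pcr)
  for (a in rownames(strata)) for (p in colnames(strata)) {
    n_s <- strata[a, p]
    expect_true(tr[a, p] %in% c(floor(n_s / 2), ceiling(n_s / 2)))
  }
})

test_that("an 83-patient cohort splits into train halves of 41 or 42", {
  cohort <- generate_trial_cohort(cohort_sim_config(seed = 2))
  cohort <- cohort[cohort$arm %in% c("TDM1P", "TH"), ]
  sizes <- vapply(1:20, function(s) nrow(split_balanced(cohort, seed = s)$train), numeric(1))
  expect_true(all(sizes %in% c(40, 41, 42, 43)))
  expect_true(median(sizes) >= 41 && median(sizes) <= 42)
  expect_identical(split_balanced(cohort, seed = 9), split_balanced(cohort, seed = 9))
})

test_that("candidate thresholds are the unique training values inside the window", {
  expect_equal(candidate_thresholds(1:10), as.numeric(2:9))
  expect_error(candidate_thresholds(rep(5, 10)), "fewer than 2")
  expect_error(candidate_thresholds(1:4), "at least 5")
  x <- c(3.2, 1.1, 4.8, 3.2, 2.5, 9.9, 0.4)
  expect_equal(candidate_thresholds(x, c(0, 100)), sort(unique(x)))
})

test_that("thresholds outside the data or leaving tiny cells are skipped", {
  cohort <- generate_trial_cohort(cohort_sim_config(seed = 3))
  sub <- cohort[cohort$arm %in% c("TDM1P", "TH"), ]
  trt <- as.numeric(sub$arm == "TDM1P")
  expect_true(is.na(interaction_p_at_threshold(sub$RAB5A, trt, sub$pcr,
                                               min(sub$RAB5A) - 1)))
  expect_true(is.na(interaction_p_at_threshold(sub$RAB5A, trt, sub$pcr,
                                               max(sub$RAB5A) + 1)))
  p <- interaction_p_at_threshold(sub$RAB5A, trt, sub$pcr, median(sub$RAB5A))
  expect_true(is.finite(p) && p > 0 && p <= 1)
})

test_that("the logit combination reproduces its defining formula", {
  res <- combine_logit(c(0.5, 0.5))
  expect_equal(res$t_stat, 0)
  expect_equal(res$p, 0.5)
  expect_equal(res$df, 14L)
  # k = 1 applied as-is: t = ln(19)/sqrt(7 pi^2 / 27), df = 9
  one <- combine_logit(0.05)
  expect_equal(one$t_stat, log(19) / sqrt(7 * pi^2 / 27), tolerance = 1e-12)
  expect_equal(one$df, 9L)
  expect_equal(one$p, pt(log(19) / sqrt(7 * pi^2 / 27), 9, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_warning(clamped <- combine_logit(c(0, 0.5)), "clamped")
  expect_true(clamped$p < 0.5)
  expect_error(combine_logit(numeric(0)), "at least one")
})

test_that("combining independent uniform p-values yields a uniform combined p", {
  ps <- withr::with_seed(77, {
    vapply(1:500, function(i) combine_logit(runif(100))$p, numeric(1))
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})

test_that("a single-iteration search returns that iteration's threshold and p", {
  cohort <- generate_trial_cohort(breakpoint_trial_config(seed = 21, n_per_arm = 60))
  res <- run_threshold_cv(cohort, config = cv_config(n_iterations = 1, seed = 4))
  it <- res$iterations
  expect_equal(nrow(it), 1)
  expect_equal(res$selected_threshold, it$selected_threshold)
  expect_equal(res$combined_p, combine_logit(it$test_p)$p)
})

test_that("the search is deterministic and invariant to patient row order", {
  cohort <- generate_trial_cohort(breakpoint_trial_config(seed = 22, n_per_arm = 60))
  cfg <- cv_config(n_iterations = 10, seed = 31)
  res1 <- run_threshold_cv(cohort, config = cfg)
  res2 <- run_threshold_cv(cohort, config = cfg)
  expect_identical(res1$iterations, res2$iterations)
  shuffled <- withr::with_seed(1, cohort[sample(nrow(cohort)), ])
  res3 <- run_threshold_cv(shuffled, config = cfg)
  expect_equal(res3$selected_threshold, res1$selected_threshold)
  expect_equal(res3$combined_p, res1$combined_p)
})

test_that("the selected threshold lies inside the pooled percentile window", {
  cohort <- generate_trial_cohort(breakpoint_trial_config(seed = 23, n_per_arm = 80))
  res <- run_threshold_cv(cohort, config = cv_config(n_iterations = 20, seed = 5))
  pooled <- cohort$RAB5A[cohort$arm %in% c("TDM1P", "TH")]
  qs <- quantile(pooled, c(0.10, 0.90), names = FALSE)
  expect_gte(res$selected_threshold, qs[1] - 1e-9)
  expect_lte(res$selected_threshold, qs[2] + 1e-9)
  expect_true(res$selected_threshold %in% as.numeric(names(res$combined_p_by_threshold)))
  expect_equal(res$combined_p, min(res$combined_p_by_threshold))
})

test_that("the training scan prefers the generative breakpoint over off-breakpoint cuts", {
  hits <- vapply(1:50, function(s) {
    cohort <- generate_trial_cohort(breakpoint_trial_config(seed = s, n_per_arm = 100))
    sub <- cohort[cohort$arm %in% c("TDM1P", "TH"), ]
    trt <- as.numeric(sub$arm == "TDM1P")
    p_at <- interaction_p_at_threshold(sub$RAB5A, trt, sub$pcr, 9.76)
    p_off <- interaction_p_at_threshold(sub$RAB5A, trt, sub$pcr, 9.76 + 0.8)
    !is.na(p_at) && (is.na(p_off) || p_at < p_off)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("config validation enforces the documented invariants", {
  expect_error(cv_config(n_iterations = 0), "positive")
  expect_error(cv_config(percentile_window = c(90, 10)), "low < high")
  expect_error(cv_config(percentile_window = c(-5, 90)), "low < high")
  cfg <- cv_config(grouping = "overall_modal")
  expect_equal(cfg$grouping, "overall_modal")
})

test_that("the modal-threshold alternative grouping is available behind its flag", {
  cohort <- generate_trial_cohort(breakpoint_trial_config(seed = 25, n_per_arm = 80))
  res <- run_threshold_cv(cohort, config = cv_config(n_iterations = 20, seed = 6,
                                                     grouping = "overall_modal"))
  counts <- table(res$iterations$selected_threshold[!is.na(res$iterations$test_p)])
  expect_equal(res$combined_p, res$combined_p_overall)
  expect_true(res$selected_threshold %in% as.numeric(names(counts)[counts == max(counts)]))
})
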