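#' Configuration for Monte-Carlo cross-validated threshold search
#'
#' @param n_iterations number of Monte-Carlo 2-fold iterations (default 100).
#' @param percentile_window candidate-threshold window as percentiles of the
#'   training expression values, default `c(10, 90)`.
#' @param seed integer RNG seed; [run_threshold_cv()] is deterministic
#'   given it.
#' @param min_group_size minimum size of every biomarker-group x arm cell a
#'   candidate threshold must leave (default 2); candidates violating it are
#'   skipped, not errors.
#' @param grouping how to reduce test-set p-values to a selected threshold:
#'   `"by_threshold"` (default) pools the test p-values of iterations that
#'   selected the same training threshold, combines each pool with the logit
#'   method, and picks the threshold with the minimum combined p;
#'   `"overall_modal"` combines all test p-values into a single p and picks
#'   the modally selected threshold.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(n_iterations = 100, percentile_window = c(10, 90),
                      seed = 1L, min_group_size = 2,
                      grouping = c("by_threshold", "overall_modal")) {
  grouping <- match.arg(grouping)
  if (!is_count(n_iterations) || n_iterations < 1)
    stop_input("'n_iterations' must be a positive integer")
  w <- percentile_window
  if (length(w) != 2 || w[1] < 0 || w[2] > 100 || w[1] >= w[2])
    stop_input("'percentile_window' must satisfy 0 <= low < high <= 100")
  if (!is_count(min_group_size)) stop_input("'min_group_size' must be a count")
  structure(list(n_iterations = as.integer(n_iterations),
                 percentile_window = w, seed = as.integer(seed),
                 min_group_size = as.integer(min_group_size),
                 grouping = grouping),
            class = "cv_config")
}

#' Split a cohort in half, balancing on arm and pCR status
#'
#' Within each arm-by-pCR stratum, half of the members (floor or ceiling at
#' random for odd strata) are assigned to the training set; the rest form
#' the test set. Train and test partition the cohort.
#'
#' @param cohort a `trial_cohort` data frame.
#' @param seed optional seed; when `NULL` (the default) the ambient RNG
#'   stream is consumed, which is how [run_threshold_cv()] drives repeated
#'   splits.
#' @return list with `train` and `test` data frames.
#' @export
split_balanced <- function(cohort, seed = NULL) {
  do_split <- function() {
    idx_train <- integer(0)
    strata <- split(seq_len(nrow(cohort)),
                    list(arm = droplevels(factor(cohort$arm)), pcr = cohort$pcr),
                    drop = TRUE)
    if (any(lengths(strata) < 2))
      warning("stratum with fewer than 2 members; it falls wholly on one side at random")
    for (ids in strata) {
      n_s <- length(ids)
      k <- n_s %/% 2L
      if (n_s %% 2L == 1L) k <- k + stats::rbinom(1L, 1L, 0.5)
      idx_train <- c(idx_train, if (k > 0) sample(ids, k) else integer(0))
    }
    idx_train
  }
  idx <- if (is.null(seed)) do_split() else withr::with_seed(as.integer(seed), do_split())
  list(train = cohort[sort(idx), , drop = FALSE],
       test = cohort[sort(setdiff(seq_len(nrow(cohort)), idx)), , drop = FALSE])
}

#' Candidate dichotomization thresholds from training expression
#'
#' Every unique observed training value between the window percentiles
#' (inclusive; percentiles by linear interpolation, R type 7), ascending.
#'
#' @param x numeric training expression values (>= 5).
#' @param percentile_window percentile bounds, default `c(10, 90)`.
#' @return ascending numeric vector of candidate thresholds.
#' @export
candidate_thresholds <- function(x, percentile_window = c(10, 90)) {
  if (length(x) < 5) stop_input("need at least 5 training values")
  qs <- stats::quantile(x, percentile_window / 100, names = FALSE, type = 7)
  cand <- sort(unique(x[x >= qs[1] & x <= qs[2]]))
  if (length(cand) < 2) stop_input("fewer than 2 candidate thresholds in the window")
  cand
}

# Fast full-vs-reduced interaction LR p for dichotomized data.
# Returns NA_real_ for degenerate candidates (undersized cells or a fit whose
# deviance fails to converge) - skipped, not errors. Boundary (quasi-separated)
# fits are retained: their deviance converges and the LR statistic is well
# defined, and small biomarker-low cells with uniform outcomes are exactly the
# configurations a dichotomizing threshold search must be able to evaluate.
interaction_lr_p <- function(high, trt, pcr, min_group_size = 2) {
  # group x arm dichotomization collapses the model to 4 binomial cells:
  # the full (group + arm + group:arm) model is saturated on them, so the LR
  # statistic equals the residual deviance of the reduced (group + arm)
  # model fitted to the aggregated cell counts.
  cell <- 2L * as.integer(high) + as.integer(trt) + 1L
  n_c <- tabulate(cell, 4L)
  if (any(n_c < min_group_size)) return(NA_real_)
  y_c <- tabulate(cell[pcr > 0], 4L)
  x_red <- cbind(1, c(0, 0, 1, 1), c(0, 1, 0, 1))  # intercept, group, arm
  red <- tryCatch(suppressWarnings(stats::glm.fit(
    x_red, y_c / n_c, weights = n_c, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 200))),
    error = function(e) NULL)
  if (is.null(red) || !red$converged) return(NA_real_)
  stats::pchisq(max(0, red$deviance), df = 1, lower.tail = FALSE)
}

#' Interaction LR p-value at a dichotomizing threshold
#'
#' Dichotomizes expression at `threshold` (Low: `x < t`, High: `x >= t`)
#' and LR-tests the group-by-treatment term in
#' `pCR ~ group + arm + group:arm`. Candidates leaving any group-by-arm
#' cell under `min_group_size`, or producing separation or non-convergence,
#' return `NA` (skipped).
#'
#' @param x numeric expression values.
#' @param trt 0/1 treatment indicator (1 = experimental arm).
#' @param pcr 0/1 outcome.
#' @param threshold dichotomization point.
#' @param min_group_size minimum cell count (default 2).
#' @return LR p-value, or `NA_real_` if the candidate is degenerate.
#' @export
interaction_p_at_threshold <- function(x, trt, pcr, threshold, min_group_size = 2) {
  interaction_lr_p(x >= threshold, as.numeric(trt), as.numeric(pcr), min_group_size)
}

#' Combine p-values with the logit method
#'
#' Computes
#' \deqn{t = -\sum_i \log\{p_i/(1-p_i)\} \Big/
#'       \sqrt{k \pi^2 (5k+2) / \{3(5k+4)\}},}
#' referred to the upper tail of a Student-t distribution with `5k + 4`
#' degrees of freedom. For `k = 1` the formula is applied as-is.
#' p-values of exactly 0 or 1 are clamped to `[1e-12, 1 - 1e-12]` with a
#' warning.
#'
#' @param pvalues numeric vector of p-values in (0, 1), `k >= 1`.
#' @return object of class `combined_p`: `k`, `t_stat`, `df`, `p`.
#' @export
combine_logit <- function(pvalues) {
  k <- length(pvalues)
  if (k < 1) stop_input("need at least one p-value")
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop_input("p-values must lie in [0, 1]")
  if (any(pvalues <= 0 | pvalues >= 1)) {
    warning("p-values at 0 or 1 clamped to [1e-12, 1 - 1e-12]")
    pvalues <- pmin(pmax(pvalues, 1e-12), 1 - 1e-12)
  }
  denom <- sqrt(k * pi^2 * (5 * k + 2) / (3 * (5 * k + 4)))
  t_stat <- -sum(log(pvalues / (1 - pvalues))) / denom
  df <- 5L * k + 4L
  structure(list(k = k, t_stat = t_stat, df = df,
                 p = stats::pt(t_stat, df = df, lower.tail = FALSE)),
            class = "combined_p")
}

#' Monte-Carlo 2-fold cross-validated threshold search
#'
#' The dichotomizing-threshold discovery procedure: for each of
#' `n_iterations` iterations, half of the cohort is selected as training
#' set (balanced on arm and pCR status); every unique training expression
#' value between the 10th and 90th percentile is scanned as a candidate
#' threshold; the candidate minimizing the training-set interaction LR
#' p-value (ties: smallest threshold) is used to dichotomize the test set,
#' where the interaction p is recorded. Test p-values are then pooled per
#' distinct selected threshold and combined with the logit method, and the
#' threshold with the minimum combined p (ties: smallest) is selected.
#'
#' Rows are sorted by `patient_id` before any randomness is consumed, so
#' the result is invariant to input row order given the seed.
#'
#' @param cohort a `trial_cohort` data frame.
#' @param marker biomarker column to dichotomize.
#' @param arms length-2 vector `(experimental, control)`.
#' @param config a [cv_config()].
#' @return object of class `threshold_search`: `iterations` (one row per
#'   iteration: selected threshold, train/test p, candidate diagnostics),
#'   `combined_p_by_threshold`, `selected_threshold`, `combined_p`,
#'   `combined_p_overall` (all test p-values combined regardless of
#'   threshold), `combination_method = "logit"`.
#' @export
run_threshold_cv <- function(cohort, marker = "RAB5A", arms = c("TDM1P", "TH"),
                             config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  sub <- cohort[cohort$arm %in% arms, , drop = FALSE]
  if (!all(arms %in% unique(as.character(sub$arm))))
    stop_input("both arms must be present in the cohort")
  sub <- sub[order(sub$patient_id), , drop = FALSE]
  trt_of <- function(d) as.numeric(d$arm == arms[1])
  iters <- withr::with_seed(config$seed, {
    lapply(seq_len(config$n_iterations), function(it) {
      sp <- split_balanced(sub)
      train <- sp$train; test <- sp$test
      cand <- tryCatch(candidate_thresholds(train[[marker]], config$percentile_window),
                       error = function(e) numeric(0))
      train_p <- vapply(cand, function(t)
        interaction_p_at_threshold(train[[marker]], trt_of(train), train$pcr,
                                   t, config$min_group_size), numeric(1))
      ok <- !is.na(train_p)
      if (!any(ok)) {
        return(data.frame(iteration = it, selected_threshold = NA_real_,
                          train_p = NA_real_, test_p = NA_real_,
                          n_candidates_evaluated = length(cand),
                          n_candidates_skipped = sum(!ok)))
      }
      best <- which(ok)[which.min(train_p[ok])]  # candidates ascending: first min = smallest
      sel <- cand[best]
      test_p <- interaction_p_at_threshold(test[[marker]], trt_of(test), test$pcr,
                                           sel, config$min_group_size)
      data.frame(iteration = it, selected_threshold = sel,
                 train_p = train_p[best], test_p = test_p,
                 n_candidates_evaluated = length(cand),
                 n_candidates_skipped = sum(!ok))
    })
  })
  iterations <- do.call(rbind, iters)
  usable <- iterations[!is.na(iterations$selected_threshold) & !is.na(iterations$test_p), ]
  if (nrow(usable) == 0) stop_input("all iterations were degenerate; no threshold can be selected")
  by_thr <- split(usable$test_p, usable$selected_threshold)
  combined <- vapply(by_thr, function(p) combine_logit(p)$p, numeric(1))
  thr_values <- as.numeric(names(combined))
  overall <- combine_logit(usable$test_p)$p
  if (config$grouping == "by_threshold") {
    sel_idx <- which(combined == min(combined))
    sel_idx <- sel_idx[which.min(thr_values[sel_idx])]  # ties: smallest threshold
    selected <- thr_values[sel_idx]
    selected_p <- combined[[sel_idx]]
  } else {
    counts <- table(usable$selected_threshold)
    modal <- as.numeric(names(counts)[counts == max(counts)])
    selected <- min(modal)
    selected_p <- overall
  }
  structure(list(iterations = iterations,
                 combined_p_by_threshold = stats::setNames(as.numeric(combined), names(combined)),
                 selected_threshold = selected,
                 combined_p = selected_p,
                 combined_p_overall = overall,
                 combination_method = "logit",
                 config = config, marker = marker, arms = arms),
            class = "threshold_search")
}

#' @export
print.threshold_search <- function(x, ...) {
  n_ok <- sum(!is.na(x$iterations$test_p))
  cat(sprintf("Monte-Carlo 2-fold CV threshold search (%d iterations, %d usable)\n",
              nrow(x$iterations), n_ok))
  cat(sprintf("  selected threshold: %.4g (combined logit-method p = %.3g)\n",
              x$selected_threshold, x$combined_p))
  cat(sprintf("  combined p over all test sets: %.3g\n", x$combined_p_overall))
  invisible(x)
}
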