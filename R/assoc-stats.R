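#' Maximum-likelihood logistic regression on a design matrix
#'
#' Thin, validated wrapper around iteratively reweighted least squares
#' (`stats::glm.fit`, binomial family, deviance tolerance 1e-10) returning
#' the quantities the association machinery needs: coefficients, standard
#' errors from the observed information, and the maximized log-likelihood.
#' Complete separation is reported via `converged = FALSE` (diagnosed by
#' fitted probabilities pinned at 0/1 together with runaway coefficients)
#' rather than an error, so callers can mark such fits as degenerate.
#'
#' @param x numeric design matrix, including any intercept column.
#' @param y binary outcome vector (0/1 or logical).
#' @return object of class `logistic_fit`: `coefficients`,
#'   `standard_errors`, `loglik`, `n`, `converged`, `design_terms`.
#' @export
fit_logistic <- function(x, y) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_input("'y' must be binary 0/1")
  if (length(unique(y)) < 2) stop_input("outcome is constant; model undefined")
  if (nrow(x) != length(y)) stop_input("design and outcome dimensions disagree")
  if (qr(x)$rank < ncol(x)) stop_input("design matrix is rank deficient")
  if (is.null(colnames(x))) colnames(x) <- paste0("b", seq_len(ncol(x)))
  fit <- suppressWarnings(stats::glm.fit(
    x, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  mu <- fit$fitted.values
  loglik <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  separated <- any(mu < 1e-8 | mu > 1 - 1e-8) && max(abs(fit$coefficients)) > 10
  p <- ncol(x)
  covmat <- tryCatch({
    R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    cm <- chol2inv(R)
    piv <- fit$qr$pivot
    cm[order(piv), order(piv), drop = FALSE]
  }, error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(covmat), 0))
  names(se) <- colnames(x)
  structure(list(coefficients = fit$coefficients,
                 standard_errors = se,
                 loglik = loglik,
                 n = length(y),
                 converged = fit$converged && !separated,
                 separated = separated,
                 design_terms = colnames(x)),
            class = "logistic_fit")
}

#' Likelihood-ratio test of nested logistic models
#'
#' `2 * (loglik_full - loglik_reduced)` (clipped at zero) referred to the
#' upper tail of a chi-square distribution with 1 degree of freedom -
#' the one-tailed LR test used throughout the qualifying-biomarker
#' analyses.
#'
#' @param full,reduced `logistic_fit` objects; `reduced` must be nested in
#'   `full` with exactly one fewer term and fitted to the same data.
#' @return list with `lr_stat` and `p`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "logistic_fit"), inherits(reduced, "logistic_fit"))
  if (full$n != reduced$n) stop_input("models were fitted to different data")
  df_diff <- length(full$coefficients) - length(reduced$coefficients)
  if (!df_diff %in% c(0L, 1L))  # 0: identical models, a valid degenerate case
    stop_input("models must differ by exactly one term")
  if (!all(reduced$design_terms %in% full$design_terms))
    stop_input("'reduced' is not nested in 'full'")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(lr_stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Shared worker: per-SD biomarker association within a subset.
# Builds full/reduced designs, standardizes the marker within the subset.
assoc_fit <- function(marker_values, pcr, extra = NULL, interaction_with = NULL,
                      label, adjusted_for_hr) {
  s <- stats::sd(marker_values)
  if (!is.finite(s) || s == 0) stop_input("biomarker is constant in the analysis subset")
  z <- (marker_values - mean(marker_values)) / s
  base <- cbind(`(Intercept)` = rep(1, length(pcr)), extra)
  if (is.null(interaction_with)) {
    x_full <- cbind(base, marker = z)
    x_red <- base
    term <- "marker"
  } else {
    x_full <- cbind(base, marker = z, trt = interaction_with,
                    `marker:trt` = z * interaction_with)
    x_red <- cbind(base, marker = z, trt = interaction_with)
    term <- "marker:trt"
  }
  full <- fit_logistic(x_full, pcr)
  red <- fit_logistic(x_red, pcr)
  lrt <- lr_test(full, red)
  coef <- unname(full$coefficients[term])
  se <- unname(full$standard_errors[term])
  structure(list(coef = coef,
                 ci95 = c(coef - 1.959964 * se, coef + 1.959964 * se),
                 odds_ratio_per_sd = exp(coef),
                 lr_stat = lrt$lr_stat,
                 p = lrt$p,
                 arm_or_contrast = label,
                 adjusted_for_hr = adjusted_for_hr,
                 n = full$n,
                 converged = full$converged && red$converged),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s%s: coef/SD = %.3f (95%% CI %.3f to %.3f), OR/SD = %.2f, LR p = %.3g (n = %d)\n",
              x$arm_or_contrast, if (x$adjusted_for_hr) " [HR-adjusted]" else "",
              x$coef, x$ci95[1], x$ci95[2], x$odds_ratio_per_sd, x$p, x$n))
  invisible(x)
}

#' Per-arm qualifying biomarker association with pCR
#'
#' Within one treatment arm, tests whether a biomarker's expression is
#' associated with pathologic complete response: the biomarker is
#' standardized to unit SD within the arm (so the coefficient is per 1 SD
#' of expression), a logistic model with and without the biomarker term is
#' fitted (the HR-status covariate retained in both when `adjust_hr`), and
#' significance is assessed by the one-tailed chi-square(1) LR test.
#'
#' @param cohort a `trial_cohort` data frame.
#' @param marker biomarker column name (e.g. `"RAB5A"`).
#' @param arm arm label to subset on.
#' @param adjust_hr adjust for hormone-receptor status?
#' @return an `association_result`.
#' @export
qualify_biomarker <- function(cohort, marker, arm, adjust_hr = FALSE) {
  if (!marker %in% names(cohort)) stop_input("unknown marker column: ", marker)
  sub <- cohort[cohort$arm == arm, , drop = FALSE]
  if (nrow(sub) < 10) stop_input("arm subset has fewer than 10 patients")
  if (length(unique(sub$pcr)) < 2) stop_input("arm subset has a constant outcome")
  extra <- if (adjust_hr) cbind(hr_neg = as.numeric(sub$hr_status == "HRneg")) else NULL
  assoc_fit(sub[[marker]], as.numeric(sub$pcr), extra = extra,
            label = arm, adjusted_for_hr = adjust_hr)
}

#' Biomarker-by-treatment interaction test
#'
#' Fits `pCR ~ marker + arm + marker:arm` (plus HR status when
#' `adjust_hr`) to the pooled patients of the two arms, with the biomarker
#' standardized to unit SD within the pooled subset, and LR-tests the
#' interaction term against chi-square(1).
#'
#' @inheritParams qualify_biomarker
#' @param arms length-2 character vector `(experimental, control)`.
#' @return an `association_result` for the interaction contrast.
#' @export
interaction_test <- function(cohort, marker, arms = c("TDM1P", "TH"), adjust_hr = FALSE) {
  if (length(arms) != 2) stop_input("'arms' must name an experimental and a control arm")
  sub <- cohort[cohort$arm %in% arms, , drop = FALSE]
  if (!all(arms %in% unique(as.character(sub$arm))))
    stop_input("both arms must be present in the cohort")
  trt <- as.numeric(sub$arm == arms[1])
  extra <- if (adjust_hr) cbind(hr_neg = as.numeric(sub$hr_status == "HRneg")) else NULL
  assoc_fit(sub[[marker]], as.numeric(sub$pcr), extra = extra, interaction_with = trt,
            label = paste0(arms[1], " x ", arms[2]), adjusted_for_hr = adjust_hr)
}

#' Association-plot summary table
#'
#' One row per marker and model (each arm's within-arm association plus the
#' treatment interaction), carrying the per-SD coefficient, its sign, the
#' odds ratio per SD, and `-log10(LR p)` - the contents of the familiar
#' circle-size/color association plot.
#'
#' @inheritParams interaction_test
#' @param markers character vector of biomarker column names.
#' @return data frame with columns `marker`, `model`, `coef`, `sign`,
#'   `odds_ratio_per_sd`, `p`, `neg_log10_p`, `adjusted_for_hr`.
#' @export
association_table <- function(cohort, markers, arms = c("TDM1P", "TH"), adjust_hr = FALSE) {
  if (length(markers) < 1) stop_input("need at least one marker")
  rows <- list()
  for (m in markers) {
    fits <- c(lapply(arms, function(a) qualify_biomarker(cohort, m, a, adjust_hr)),
              list(interaction_test(cohort, m, arms, adjust_hr)))
    for (f in fits) {
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, model = f$arm_or_contrast, coef = f$coef,
        sign = sign(f$coef), odds_ratio_per_sd = f$odds_ratio_per_sd,
        p = f$p, neg_log10_p = -log10(f$p), adjusted_for_hr = f$adjusted_for_hr,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test with the minimum-likelihood two-sided rule:
#' the p-value sums the probabilities of all tables (margins fixed) whose
#' point probability does not exceed the observed table's.
#'
#' @param a,b,c,d cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_input("cell counts must be non-negative integers")
  if (sum(counts) == 0) stop_input("table total must be positive")
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("a margin is zero; p = 1 by convention")
    return(1)
  }
  stats::fisher.test(m)$p.value
}

#' Mann-Whitney rank-sum test
#'
#' Exact null distribution when `length(x) * length(y) <= 400` and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction. `U` counts pairs `(x_i, y_j)` with `x_i > y_j` (ties count
#' one half).
#'
#' @param x,y numeric samples, both non-empty.
#' @return list with `U` and two-sided `p`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop_input("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) * length(y) <= 400) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}
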