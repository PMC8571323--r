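#' Bayesian subgroup model settings
#'
#' Independent Normal priors on every coefficient and the chain schedule of
#' the covariate-adjusted logistic model: 1000 adaptation iterations, 5000
#' burn-in, 10,000 retained draws.
#'
#' @param n_keep retained posterior draws (default 10000).
#' @param n_adapt step-size adaptation iterations (default 1000).
#' @param n_burnin post-adaptation burn-in iterations (default 5000).
#' @param prior_mean,prior_sd Normal prior for each coefficient
#'   (default N(0, 1)).
#' @param seed integer RNG seed.
#' @return object of class `bayes_model_spec`.
#' @export
bayes_model_spec <- function(n_keep = 10000, n_adapt = 1000, n_burnin = 5000,
                             prior_mean = 0, prior_sd = 1, seed = 1L) {
  for (n in c(n_keep, n_adapt, n_burnin))
    if (!is_count(n) || n < 1) stop_input("chain lengths must be positive integers")
  if (prior_sd <= 0) stop_input("'prior_sd' must be > 0")
  structure(list(n_keep = as.integer(n_keep), n_adapt = as.integer(n_adapt),
                 n_burnin = as.integer(n_burnin), prior_mean = prior_mean,
                 prior_sd = prior_sd, seed = as.integer(seed)),
            class = "bayes_model_spec")
}

#' Build the saturated subtype-by-treatment design
#'
#' Subtypes are the four combinations of HR status and biomarker group
#' (High: `x >= threshold`); in an all-HER2-positive cohort HER2 status is
#' constant and absorbed. The linear predictor is saturated in subtype and
#' treatment,
#' \deqn{\eta = \alpha_s + \gamma_s \, 1[\mathrm{arm} = \mathrm{experimental}],}
#' i.e. a subtype-specific intercept and a subtype-specific treatment
#' effect - 8 coefficients for 4 subtypes x 2 arms. Empty subtypes are
#' retained (their coefficients are then prior-dominated) with a warning.
#'
#' @param cohort a `trial_cohort` data frame.
#' @param threshold biomarker dichotomization threshold.
#' @param marker biomarker column (default `"RAB5A"`).
#' @param arms length-2 vector `(experimental, control)`.
#' @return object of class `subtype_design`: design matrix `x` (columns
#'   `alpha:<subtype>` then `gamma:<subtype>`), outcome `y`, `subtype`
#'   factor, treatment indicator `trt`, `group` factor (High/Low),
#'   `subtype_levels`, `arms`.
#' @export
build_subtype_design <- function(cohort, threshold, marker = "RAB5A",
                                 arms = c("TDM1P", "TH")) {
  sub <- cohort[cohort$arm %in% arms, , drop = FALSE]
  if (nrow(sub) == 0) stop_input("no patients in the requested arms")
  group <- factor(ifelse(sub[[marker]] >= threshold, "High", "Low"),
                  levels = c("High", "Low"))
  lev <- c("HRpos/High", "HRpos/Low", "HRneg/High", "HRneg/Low")
  subtype <- factor(paste(sub$hr_status, group, sep = "/"), levels = lev)
  if (any(table(subtype) == 0))
    warning("empty subtype(s): ",
            paste(lev[table(subtype) == 0], collapse = ", "),
            "; their coefficients are prior-dominated")
  trt <- as.numeric(sub$arm == arms[1])
  alpha <- stats::model.matrix(~ subtype - 1)
  colnames(alpha) <- paste0("alpha:", lev)
  gamma <- alpha * trt
  colnames(gamma) <- paste0("gamma:", lev)
  structure(list(x = cbind(alpha, gamma), y = as.numeric(sub$pcr),
                 subtype = subtype, trt = trt, group = group,
                 subtype_levels = lev, arms = arms),
            class = "subtype_design")
}

#' Sample the posterior by componentwise adaptive random-walk Metropolis
#'
#' Bayesian logistic regression with independent Normal priors. Each
#' coefficient is updated in turn by a Gaussian random-walk proposal; during
#' the adaptation phase the per-coordinate step size is tuned toward a
#' 40-50% acceptance rate (multiplied by 1.2 / divided by 1.2 every 50
#' iterations when the block acceptance leaves that band), then frozen.
#' Burn-in draws are discarded; with zero data rows the chain samples the
#' prior. Fully deterministic given `spec$seed`.
#'
#' @param spec a [bayes_model_spec()].
#' @param design a `subtype_design`, or a plain numeric design matrix.
#' @param outcomes binary outcome vector; taken from `design$y` when the
#'   design is a `subtype_design`.
#' @return `n_keep` x p matrix of posterior draws (class
#'   `posterior_draws`), with attributes `acceptance` (post-adaptation
#'   acceptance rate per coordinate) and `step_sizes`.
#' @export
sample_posterior <- function(spec, design, outcomes = NULL) {
  stopifnot(inherits(spec, "bayes_model_spec"))
  if (inherits(design, "subtype_design")) {
    x <- design$x
    y <- design$y
  } else {
    x <- as.matrix(design)
    y <- as.numeric(outcomes)
  }
  p <- ncol(x)
  n <- nrow(x)
  if (n > 0 && length(y) != n) stop_input("design and outcomes disagree")
  nz <- lapply(seq_len(p), function(j) which(x[, j] != 0))
  withr::with_seed(spec$seed, {
    beta <- rep(spec$prior_mean, p)
    eta <- if (n > 0) as.vector(x %*% beta) else numeric(0)
    step <- rep(2.4 * spec$prior_sd, p)
    n_total <- spec$n_adapt + spec$n_burnin + spec$n_keep
    draws <- matrix(NA_real_, spec$n_keep, p, dimnames = list(NULL, colnames(x)))
    acc_block <- numeric(p)
    acc_keep <- numeric(p)
    n_keep_updates <- 0L
    for (iter in seq_len(n_total)) {
      adapting <- iter <= spec$n_adapt
      keeping <- iter > spec$n_adapt + spec$n_burnin
      for (j in seq_len(p)) {
        prop <- beta[j] + step[j] * stats::rnorm(1L)
        dprior <- -0.5 * ((prop - spec$prior_mean)^2 - (beta[j] - spec$prior_mean)^2) / spec$prior_sd^2
        rows <- nz[[j]]
        if (length(rows)) {
          deta <- (prop - beta[j]) * x[rows, j]
          eta_new <- eta[rows] + deta
          dll <- sum(y[rows] * deta) - sum(softplus(eta_new) - softplus(eta[rows]))
        } else {
          dll <- 0
        }
        if (log(stats::runif(1L)) < dll + dprior) {
          beta[j] <- prop
          if (length(rows)) eta[rows] <- eta_new
          if (adapting) acc_block[j] <- acc_block[j] + 1
          if (keeping) acc_keep[j] <- acc_keep[j] + 1
        }
      }
      if (adapting && iter %% 50L == 0L) {
        rate <- acc_block / 50
        step[rate > 0.5] <- step[rate > 0.5] * 1.2
        step[rate < 0.4] <- step[rate < 0.4] / 1.2
        acc_block[] <- 0
      }
      if (keeping) {
        n_keep_updates <- n_keep_updates + 1L
        draws[n_keep_updates, ] <- beta
      }
    }
  })
  structure(draws, class = c("posterior_draws", "matrix"),
            acceptance = acc_keep / spec$n_keep, step_sizes = step)
}

#' Posterior pCR probability for an arm, overall or within a subgroup
#'
#' For each posterior draw, the arm-level pCR probability is the mixture
#' \deqn{\sum_s w_s \, \mathrm{invlogit}(\alpha_s + \gamma_s T)}
#' over subtypes `s`, with weights `w_s` equal to the observed subtype
#' proportions within the arm-and-subset patients and `T` the treatment
#' indicator of the requested arm. Reported are the posterior mean and the
#' central 95% probability interval (2.5th/97.5th percentiles of the
#' draws).
#'
#' @param draws a `posterior_draws` matrix from [sample_posterior()].
#' @param design the `subtype_design` the draws were sampled under.
#' @param arm arm label (must be one of `design$arms`).
#' @param subset `"all"`, a biomarker group (`"High"`/`"Low"`), or a single
#'   subtype label such as `"HRneg/High"`.
#' @return object of class `posterior_summary`: `mean_prob`, `pi95`,
#'   `n_draws`, `subset_label`, `arm`, `weights`.
#' @export
estimate_pcr <- function(draws, design, arm, subset = "all") {
  stopifnot(inherits(design, "subtype_design"))
  if (!arm %in% design$arms) stop_input("'arm' must be one of the design arms")
  trt_val <- as.numeric(arm == design$arms[1])
  in_arm <- design$trt == trt_val
  keep <- if (identical(subset, "all")) {
    in_arm
  } else if (subset %in% c("High", "Low")) {
    in_arm & design$group == subset
  } else if (subset %in% design$subtype_levels) {
    in_arm & design$subtype == subset
  } else {
    stop_input("unknown subset: ", subset)
  }
  if (!any(keep)) stop_input("subset '", subset, "' is empty in arm ", arm)
  w <- table(design$subtype[keep]) / sum(keep)
  lev <- design$subtype_levels
  probs <- numeric(nrow(draws))
  for (s in lev[w > 0]) {
    eta <- draws[, paste0("alpha:", s)] + draws[, paste0("gamma:", s)] * trt_val
    probs <- probs + as.numeric(w[s]) * invlogit(eta)
  }
  qs <- stats::quantile(probs, c(0.025, 0.975), names = FALSE)
  structure(list(mean_prob = mean(probs), pi95 = qs, n_draws = nrow(draws),
                 subset_label = subset, arm = arm, weights = w),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("arm %s, subset %s: estimated pCR probability %.0f%% (95%% PI: %.0f-%.0f%%)\n",
              x$arm, x$subset_label, 100 * x$mean_prob, 100 * x$pi95[1], 100 * x$pi95[2]))
  invisible(x)
}
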