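# Shared fixtures and independent oracles used across test files.

# Null-structured trial config: no biomarker effect, no interaction, arm
# rates near the observed 30/52 vs 8/31.
null_trial_config <- function(seed, n_tdm1p = 52, n_th = 31) {
  cohort_sim_config(
    n_per_arm = c(TDM1P = n_tdm1p, TH = n_th, THP = 0),
    biomarker_mean = c(TDM1P = 10.35, TH = 11.0, THP = 10.5),
    beta0 = -1.05, beta_arm = 1.36, beta_marker = 0, beta_interaction = 0,
    beta_hr = 0.4, seed = seed)
}

# Step-interaction config used by breakpoint-recovery experiments: both arms
# share a well-populated biomarker distribution around the breakpoint and the
# treatment effect jumps at it.
breakpoint_trial_config <- function(seed, n_per_arm = 150, breakpoint = 9.76,
                                    beta_interaction = 3.5) {
  cohort_sim_config(
    n_per_arm = c(TDM1P = n_per_arm, TH = n_per_arm, THP = 0),
    biomarker_mean = c(TDM1P = 10, TH = 10, THP = 10),
    interaction_form = "step", breakpoint = breakpoint,
    beta_interaction = beta_interaction, beta_arm = -0.5,
    beta_marker = 0, beta0 = -1.05, beta_hr = 0.4, seed = seed)
}

# Independent log-likelihood for a logistic model (used by grid oracles).
loglik_logistic <- function(beta, x, y) {
  eta <- as.vector(x %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# Nested coarse-to-fine grid maximization of the logistic likelihood,
# independent of glm/IRLS. Two-parameter designs only.
grid_max_loglik <- function(x, y, lower = -5, upper = 5, levels = 6, width = 10) {
  center <- c(0, 0)
  for (lev in seq_len(levels)) {
    g1 <- seq(center[1] - width / 2, center[1] + width / 2, length.out = 21)
    g2 <- seq(center[2] - width / 2, center[2] + width / 2, length.out = 21)
    ll <- outer(g1, g2, Vectorize(function(a, b) loglik_logistic(c(a, b), x, y)))
    idx <- arrayInd(which.max(ll), dim(ll))
    center <- c(g1[idx[1]], g2[idx[2]])
    width <- width / 5
  }
  loglik_logistic(center, x, y)
}

# Mann-Whitney U (pairs with x > y, ties one half), independent of wilcox.test.
u_statistic <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
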