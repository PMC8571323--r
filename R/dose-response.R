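#' Fit the sigmoid viability model to a dose-response series
#'
#' Least-squares fit of the three-parameter sigmoid
#' \deqn{v = a / (1 + \exp(-(x - x_0)/b)),}
#' where `v` is the viability fraction and `x = log10(concentration)`.
#' Doses typically span several decades, so the abscissa is taken on the
#' log10 scale; `a` is the upper asymptote, `x0` the inflection location and
#' `b` the slope scale (negative for viability falling with dose; the sign
#' is unconstrained).
#'
#' Fitting is multi-start Levenberg-Marquardt: starts are laid on a coarse
#' grid over `x0` (spanning the observed dose range) and `b`, with `a`
#' started at the maximum observed viability; the best residual sum of
#' squares wins. The `converged` flag is honest - if no start converges the
#' best start's parameters are returned with `converged = FALSE`.
#'
#' @param concentrations dose vector in ug/ml, all positive, with at least
#'   4 distinct values.
#' @param viabilities viability fractions (same length).
#' @return an object of class `sigmoid_fit`: list with `a`, `x0`, `b`,
#'   `ic50` (`NA` when undefined, see [ic50_from_fit()]), `rss`,
#'   `converged`, `n`.
#' @examples
#' x <- 10^seq(-3, 1, length.out = 8)
#' v <- 1 / (1 + exp(-(log10(x) - (-1)) / -0.5))
#' fit_sigmoid(x, v)
#' @export
fit_sigmoid <- function(concentrations, viabilities) {
  if (length(concentrations) != length(viabilities))
    stop_input("'concentrations' and 'viabilities' must have equal length")
  if (any(concentrations <= 0)) stop_input("concentrations must be > 0")
  if (length(unique(concentrations)) < 4)
    stop_input("need at least 4 distinct concentrations")
  x <- log10(concentrations)
  v <- viabilities
  a_start <- max(v, 0.1)
  x0_grid <- stats::quantile(x, c(0.15, 0.35, 0.5, 0.65, 0.85), names = FALSE)
  b_grid <- c(-1, -0.5, -0.2, 0.5)
  best <- NULL
  for (x0s in x0_grid) for (bs in b_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ a / (1 + exp(-(x - x0) / b)),
        start = list(a = a_start, x0 = x0s, b = bs),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    conv <- fit$convInfo$isConv
    if (is.null(best) || rss < best$rss - 1e-14 || (conv && !best$converged && rss <= best$rss + 1e-14)) {
      cf <- stats::coef(fit)
      best <- list(a = unname(cf["a"]), x0 = unname(cf["x0"]), b = unname(cf["b"]),
                   rss = rss, converged = isTRUE(conv))
    }
  }
  if (is.null(best)) {
    best <- list(a = a_start, x0 = stats::median(x), b = -0.5,
                 rss = sum((v - mean(v))^2), converged = FALSE)
  }
  out <- structure(c(best, list(n = length(v))), class = "sigmoid_fit")
  out$ic50 <- if (out$converged && out$a > 0.5) ic50_from_fit(out) else NA_real_
  out
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid fit: a = %.4g, x0 = %.4g, b = %.4g, rss = %.3g (%s)\n",
              x$a, x$x0, x$b, x$rss, if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  IC50 = %s ug/ml\n", if (is.na(x$ic50)) "undefined" else format(x$ic50, digits = 4)))
  invisible(x)
}

#' Extract the IC50 from a fitted sigmoid
#'
#' The IC50 is the concentration at which the fitted curve equals an
#' absolute viability of 0.5 (half of untreated control), not half of the
#' fitted asymptote: solving `a / (1 + exp(-(x - x0)/b)) = 0.5` gives
#' `x* = x0 - b * log(a/0.5 - 1)` and `IC50 = 10^x*`. A curve with
#' `a <= 0.5` never reaches half-maximal inhibition and raises an error.
#'
#' @param fit a `sigmoid_fit` (must have converged).
#' @return IC50 in ug/ml.
#' @export
ic50_from_fit <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!fit$converged) stop_input("fit did not converge; IC50 undefined")
  if (fit$a <= 0.5) stop_input("curve never reaches 50% viability (a <= 0.5)")
  10^(fit$x0 - fit$b * log(fit$a / 0.5 - 1))
}

#' Per-line IC50 summary from long-format viability data
#'
#' Fits the sigmoid model separately to each experiment (replicate) of each
#' cell line and averages the per-experiment IC50s - independent experiments
#' are fitted individually rather than pooled.
#'
#' @param viability long-format data frame with columns `cell_line`,
#'   `concentration`, `replicate`, `viability` (a `drug` column is carried
#'   through if present).
#' @return data frame with one row per cell line: `cell_line`, `ic50`
#'   (mean over converged experiments), `n_experiments`, `n_converged`.
#' @export
ic50_summary <- function(viability) {
  need <- c("cell_line", "concentration", "replicate", "viability")
  if (!all(need %in% names(viability)))
    stop_input("viability table needs columns: ", paste(need, collapse = ", "))
  res <- lapply(split(viability, viability$cell_line), function(d) {
    ics <- vapply(split(d, d$replicate), function(r) {
      fit <- fit_sigmoid(r$concentration, r$viability)
      if (fit$converged && !is.na(fit$ic50)) fit$ic50 else NA_real_
    }, numeric(1))
    data.frame(cell_line = d$cell_line[1],
               ic50 = mean(ics, na.rm = TRUE),
               n_experiments = length(ics),
               n_converged = sum(!is.na(ics)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Regress drug sensitivity on biomarker expression
#'
#' Ordinary least squares of sensitivity `y = 1/IC50` on expression `x`,
#' with `R^2` equal to the squared Pearson correlation. With only two
#' points the fit is saturated and `R^2 = 1` by construction.
#'
#' @param expression numeric vector of relative expression values.
#' @param ic50s positive IC50s, same length (>= 2).
#' @return an object of class `linear_fit`: `slope`, `intercept`, `r2`, `n`.
#' @export
sensitivity_regression <- function(expression, ic50s) {
  if (length(expression) != length(ic50s) || length(expression) < 2)
    stop_input("need equal-length vectors with at least 2 points")
  if (any(ic50s <= 0)) stop_input("IC50s must be > 0")
  if (stats::sd(expression) == 0) stop_input("expression has zero variance")
  y <- 1 / ic50s
  fit <- stats::lm(y ~ expression)
  r2 <- if (stats::sd(y) == 0) 1 else stats::cor(expression, y)^2
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, n = length(y)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("1/IC50 = %.4g * expression + %.4g  (R^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}
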