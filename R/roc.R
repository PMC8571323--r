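#' ROC curve of a continuous score against a binary outcome
#'
#' Thresholds are placed at the midpoints between consecutive distinct
#' scores, plus `-Inf` and `+Inf` endpoints; a case is called positive when
#' its score is greater than or equal to the threshold (higher expression
#' predicts response). The AUC is computed by the trapezoidal rule over
#' (1 - specificity, sensitivity), which equals the Mann-Whitney
#' U-statistic divided by `n_pos * n_neg` with ties counted one half. An
#' AUC below 0.5 is reported as-is (the score is anti-predictive in that
#' direction), never flipped.
#'
#' @param scores numeric vector (e.g. biomarker expression).
#' @param labels binary outcome (logical or 0/1); both classes must be
#'   present.
#' @return object of class `roc_curve`: `points` (data frame with
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop_input("'scores' and 'labels' lengths differ")
  if (!any(labels) || all(labels)) stop_input("both outcome classes must be present")
  ds <- sort(unique(scores))
  thr <- c(-Inf, if (length(ds) > 1) (ds[-1] + ds[-length(ds)]) / 2, Inf)
  pos <- scores[labels]
  neg <- scores[!labels]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  # thresholds ascend, so fpr and sens both descend; integrate along that path
  fpr <- 1 - spec
  ord <- rev(seq_along(thr))
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, n_pos = length(pos), n_neg = length(neg)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.3f (%d positives, %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Optimal ROC cutoff by the Youden index
#'
#' Returns the threshold maximizing `sensitivity + specificity - 1`; on
#' ties, the smallest threshold.
#'
#' @param curve a `roc_curve`.
#' @return the optimal threshold (one of the curve's threshold points).
#' @export
optimal_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$points$sensitivity + curve$points$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  min(curve$points$threshold[best])
}
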