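#' Total Allred score from intensity and proportion components
#'
#' The Allred system scores staining intensity 0-3 (negative, weak,
#' intermediate, strong) and the proportion of stained cells 0-5 (none,
#' <=1%, 1-10%, 11-33%, 34-66%, 67-100%); the total is their sum (0, 2-8;
#' a total of 1 is unreachable). A tumor with no stained cells must score 0
#' on both components, so `(intensity > 0, proportion = 0)` and
#' `(intensity = 0, proportion > 0)` are validation errors.
#'
#' @param intensity integer vector in 0:3.
#' @param proportion integer vector in 0:5, same length.
#' @return integer vector of total scores.
#' @examples
#' allred_total(3, 5)  # 8
#' @export
allred_total <- function(intensity, proportion) {
  if (length(intensity) != length(proportion)) stop_input("component lengths differ")
  if (!all(intensity %in% 0:3)) stop_input("'intensity' must be integers in 0:3")
  if (!all(proportion %in% 0:5)) stop_input("'proportion' must be integers in 0:5")
  if (any((proportion == 0) != (intensity == 0)))
    stop_input("inconsistent components: proportion 0 requires intensity 0 and vice versa")
  as.integer(intensity + proportion)
}

#' Dichotomize Allred totals into High/Low expression groups
#'
#' @param total integer vector of total Allred scores (0, 2-8).
#' @param high_scores totals labelled High; default `c(7, 8)`.
#' @return factor with levels `High`, `Low`.
#' @export
dichotomize_allred <- function(total, high_scores = c(7, 8)) {
  if (!all(total %in% c(0, 2:8))) stop_input("invalid Allred totals")
  factor(ifelse(total %in% high_scores, "High", "Low"), levels = c("High", "Low"))
}

#' Compare progression-free survival between Allred groups
#'
#' Mann-Whitney rank-sum comparison of PFS between the High and Low
#' expression groups, with group medians. PFS is treated as observed (no
#' censoring adjustment), matching a rank-sum analysis of recorded
#' follow-up times.
#'
#' @param group factor of `High`/`Low` labels (e.g. from
#'   [dichotomize_allred()]).
#' @param pfs_weeks positive PFS values, same length.
#' @return list with `U`, `p`, and `medians` (named: High, Low), plus the
#'   per-group PFS listings for plotting.
#' @export
compare_pfs <- function(group, pfs_weeks) {
  if (length(group) != length(pfs_weeks)) stop_input("lengths differ")
  group <- factor(group, levels = c("High", "Low"))
  hi <- pfs_weeks[group == "High"]
  lo <- pfs_weeks[group == "Low"]
  if (length(hi) == 0 || length(lo) == 0) stop_input("both groups must be non-empty")
  mw <- mann_whitney(hi, lo)
  list(U = mw$U, p = mw$p,
       medians = c(High = stats::median(hi), Low = stats::median(lo)),
       pfs = list(High = hi, Low = lo))
}
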