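#' Inverse-logit transform
#'
#' @param x numeric vector on the logit scale.
#' @return `exp(x) / (1 + exp(x))`, computed stably for large `|x|`.
#' @keywords internal
invlogit <- function(x) {
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

# log(1 + exp(x)) without overflow; exact to double precision for x > 33
softplus <- function(x) {
  ifelse(x > 33, x, log1p(exp(x)))
}

# Scalar integer-ish check used by config validators
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

stop_input <- function(...) {
  stop(..., call. = FALSE)
}

# Arm / factor level constants shared across modules
ARM_LEVELS <- c("TDM1P", "TH", "THP")
HR_LEVELS <- c("HRpos", "HRneg")
PLATFORM_LEVELS <- c("P15746", "P32627")
MARKERS <- c("RAB4A", "RAB5A", "RAB11A", "ERBB2")
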