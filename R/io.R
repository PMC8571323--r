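#' Write a trial cohort to CSV
#'
#' Columns are `patient_id,arm,hr_status,pcr,platform,RAB4A,RAB5A,RAB11A,ERBB2`
#' with the pCR indicator written as 0/1.
#'
#' @param cohort a `trial_cohort` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$pcr <- as.integer(out$pcr)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial cohort from CSV
#'
#' Inverse of [write_cohort()]; also accepts externally prepared patient
#' tables with the same header.
#'
#' @param path CSV file path.
#' @return a `trial_cohort` data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "arm", "hr_status", "pcr", "platform", MARKERS)
  missing <- setdiff(need, names(df))
  if (length(missing)) stop_input("cohort file lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$patient_id)) stop_input("patient_id values must be unique")
  if (!all(df$arm %in% ARM_LEVELS)) stop_input("unknown arm labels in cohort file")
  if (!all(df$hr_status %in% HR_LEVELS)) stop_input("unknown hr_status labels")
  expr <- as.matrix(df[, MARKERS])
  if (!all(is.finite(expr))) stop_input("expression values must all be finite")
  df$pcr <- df$pcr == 1 | df$pcr == "TRUE" | df$pcr == TRUE
  df$arm <- factor(df$arm, levels = ARM_LEVELS[ARM_LEVELS %in% unique(df$arm)])
  df$hr_status <- factor(df$hr_status, levels = HR_LEVELS)
  df$platform <- factor(df$platform, levels = PLATFORM_LEVELS)
  attr(df, "provenance") <- path
  class(df) <- c("trial_cohort", "data.frame")
  df
}

# Dispatch YAML vs JSON on extension
read_config_file <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop_input("config must be .yaml/.yml or .json, got: .", ext)
  }
}
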