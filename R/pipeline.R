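#' Cross-tabulate arm, biomarker group and pCR (mosaic counts)
#'
#' Counts patients in every arm-by-group-by-pCR cell after dichotomizing
#' expression at `threshold` (Low: `x < t`); the counts partition the
#' cohort exactly.
#'
#' @param cohort a `trial_cohort` data frame.
#' @param threshold dichotomization threshold.
#' @param marker biomarker column (default `"RAB5A"`).
#' @param arms arms to include; default all arms present.
#' @return data frame with columns `arm`, `group`, `pcr`, `count`.
#' @export
mosaic_counts <- function(cohort, threshold, marker = "RAB5A", arms = NULL) {
  if (is.null(arms)) arms <- levels(droplevels(factor(cohort$arm)))
  sub <- cohort[cohort$arm %in% arms, , drop = FALSE]
  group <- factor(ifelse(sub[[marker]] >= threshold, "High", "Low"),
                  levels = c("High", "Low"))
  tab <- table(arm = factor(sub$arm, levels = arms), group = group,
               pcr = factor(sub$pcr, levels = c(FALSE, TRUE)))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("arm", "group", "pcr", "count")
  out$pcr <- out$pcr == "TRUE"
  out
}

# default pipeline configuration; user config entries override these
default_pipeline_config <- function() {
  list(seed = 1L,
       outdir = NULL,
       stages = c("simulate", "qualify", "threshold_cv", "balance",
                  "bayes", "roc", "invitro", "allred"),
       cohort_file = NULL,
       marker = "RAB5A",
       arms = c("TDM1P", "TH"),
       threshold_override = NULL,
       cohort_sim = list(),
       cellline_sim = list(),
       ihc_sim = list(),
       cv = list(),
       bayes = list())
}

#' Run the full biomarker-qualification pipeline
#'
#' Executes the requested stages in order - simulate/ingest, per-arm
#' qualification and interaction testing, Monte-Carlo CV threshold search,
#' balance checks and mosaic counts, Bayesian subgroup estimation, ROC
#' analysis, in-vitro IC50/regression, and the Allred/PFS comparison - and
#' writes a machine-readable JSON report plus CSV tables to the output
#' directory. The report contains no timestamps, so a rerun with the same
#' configuration is byte-identical.
#'
#' @param config a named list, or path to a YAML/JSON file, overriding any
#'   of: `seed`, `outdir`, `stages`, `cohort_file` (CSV of patient records;
#'   when `NULL` a cohort is simulated), `marker`, `arms`,
#'   `threshold_override` (skip the CV search and use this threshold),
#'   `cohort_sim` / `cellline_sim` / `ihc_sim` (generator arguments),
#'   `cv` ([cv_config()] arguments), `bayes` ([bayes_model_spec()]
#'   arguments).
#' @param quiet suppress stage log messages.
#' @return the report, invisibly (a named list mirroring `report.json`).
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- read_config_file(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (is.null(cfg$outdir)) cfg$outdir <- tempfile("pipeline-")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (!quiet) message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                               " [pipeline] ", ...)
  report <- list(schema_version = 1L, seed = cfg$seed, marker = cfg$marker,
                 arms = cfg$arms, stages = list())
  run_stage <- function(name, fn) {
    if (!name %in% cfg$stages) return(NULL)
    log_msg("stage ", name)
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # --- cohort: ingest or simulate -------------------------------------------
  cohort <- if (!is.null(cfg$cohort_file)) {
    log_msg("reading cohort from ", cfg$cohort_file)
    read_cohort(cfg$cohort_file)
  } else {
    log_msg("simulating cohort (seed ", cfg$seed, ")")
    sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$cohort_sim)
    for (f in c("n_per_arm", "biomarker_mean"))  # YAML/JSON deliver these as lists
      if (!is.null(sim_args[[f]])) sim_args[[f]] <- unlist(sim_args[[f]])
    generate_trial_cohort(do.call(cohort_sim_config, sim_args), marker = cfg$marker)
  }
  write_cohort(cohort, file.path(cfg$outdir, "cohort.csv"))
  report$stages$cohort <- list(
    n = nrow(cohort),
    arm_sizes = as.list(table(cohort$arm)),
    pcr_by_arm = lapply(split(cohort$pcr, cohort$arm), function(p) sum(p)))

  # --- qualify ---------------------------------------------------------------
  run_stage("qualify", function() {
    tab <- rbind(association_table(cohort, MARKERS[MARKERS != "ERBB2"], cfg$arms, adjust_hr = FALSE),
                 association_table(cohort, MARKERS[MARKERS != "ERBB2"], cfg$arms, adjust_hr = TRUE))
    utils::write.csv(tab, file.path(cfg$outdir, "association_table.csv"), row.names = FALSE)
    marker_rows <- tab[tab$marker == cfg$marker & !tab$adjusted_for_hr, ]
    report$stages$qualify <<- list(
      table_file = "association_table.csv",
      marker_p_by_model = stats::setNames(as.list(marker_rows$p), marker_rows$model))
  })

  # --- threshold search ------------------------------------------------------
  threshold <- cfg$threshold_override
  run_stage("threshold_cv", function() {
    if (!is.null(cfg$threshold_override)) {
      report$stages$threshold_cv <<- list(threshold = cfg$threshold_override,
                                          source = "override")
      return(NULL)
    }
    cv_args <- utils::modifyList(list(seed = cfg$seed), cfg$cv)
    res <- run_threshold_cv(cohort, cfg$marker, cfg$arms, do.call(cv_config, cv_args))
    utils::write.csv(res$iterations, file.path(cfg$outdir, "cv_iterations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(selected_threshold = res$selected_threshold,
           combined_p = res$combined_p,
           combined_p_overall = res$combined_p_overall,
           combined_p_by_threshold = as.list(res$combined_p_by_threshold)),
      file.path(cfg$outdir, "threshold_cv.json"), auto_unbox = TRUE, digits = NA)
    threshold <<- res$selected_threshold
    report$stages$threshold_cv <<- list(threshold = res$selected_threshold,
                                        combined_p = res$combined_p,
                                        combined_p_overall = res$combined_p_overall,
                                        source = "cv")
  })

  # --- balance checks + mosaic ----------------------------------------------
  run_stage("balance", function() {
    if (is.null(threshold)) stop("balance stage needs a threshold (run threshold_cv or set an override)")
    mc <- mosaic_counts(cohort, threshold, cfg$marker, cfg$arms)
    utils::write.csv(mc, file.path(cfg$outdir, "mosaic_counts.csv"), row.names = FALSE)
    exp_arm <- cohort[cohort$arm == cfg$arms[1], ]
    grp_high <- exp_arm[[cfg$marker]] >= threshold
    hr_neg <- exp_arm$hr_status == "HRneg"
    fisher_p <- fisher_exact_2x2(sum(hr_neg & grp_high), sum(!hr_neg & grp_high),
                                 sum(hr_neg & !grp_high), sum(!hr_neg & !grp_high))
    erbb2_p <- mann_whitney(exp_arm$ERBB2[grp_high], exp_arm$ERBB2[!grp_high])$p
    report$stages$balance <<- list(threshold = threshold,
                                   hr_fisher_p = fisher_p,
                                   erbb2_rank_p = erbb2_p,
                                   mosaic_file = "mosaic_counts.csv")
  })

  # --- Bayesian subgroup estimates ------------------------------------------
  run_stage("bayes", function() {
    if (is.null(threshold)) stop("bayes stage needs a threshold")
    spec <- do.call(bayes_model_spec, utils::modifyList(list(seed = cfg$seed), cfg$bayes))
    design <- build_subtype_design(cohort, threshold, cfg$marker, cfg$arms)
    draws <- sample_posterior(spec, design)
    rows <- list()
    for (arm in cfg$arms) for (ss in c("all", "High", "Low")) {
      est <- estimate_pcr(draws, design, arm, ss)
      rows[[paste(arm, ss)]] <- data.frame(arm = arm, subset = ss,
                                           mean_prob = est$mean_prob,
                                           pi_low = est$pi95[1], pi_high = est$pi95[2])
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    utils::write.csv(tab, file.path(cfg$outdir, "bayes_summary.csv"), row.names = FALSE)
    report$stages$bayes <<- list(summary = lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, ])))
  })

  # --- ROC -------------------------------------------------------------------
  run_stage("roc", function() {
    out <- list()
    for (arm in cfg$arms) {
      sub <- cohort[cohort$arm == arm, ]
      rc <- roc_curve(sub[[cfg$marker]], sub$pcr)
      utils::write.csv(rc$points, file.path(cfg$outdir, paste0("roc_", arm, ".csv")),
                       row.names = FALSE)
      out[[arm]] <- list(auc = rc$auc, optimal_cutoff = optimal_cutoff(rc))
    }
    report$stages$roc <<- out
  })

  # --- in-vitro panel --------------------------------------------------------
  run_stage("invitro", function() {
    args <- utils::modifyList(list(seed = cfg$seed), cfg$cellline_sim)
    panel <- do.call(generate_cellline_panel, args)
    ics <- ic50_summary(panel$viability)
    utils::write.csv(ics, file.path(cfg$outdir, "ic50_summary.csv"), row.names = FALSE)
    fit <- sensitivity_regression(panel$lines[[panel$marker]], ics$ic50)
    report$stages$invitro <<- list(r2 = fit$r2, slope = fit$slope,
                                   intercept = fit$intercept,
                                   n_lines = nrow(panel$lines),
                                   ic50_file = "ic50_summary.csv")
  })

  # --- Allred / PFS ----------------------------------------------------------
  run_stage("allred", function() {
    args <- utils::modifyList(list(seed = cfg$seed), cfg$ihc_sim)
    ihc <- do.call(generate_ihc_cohort, args)
    grp <- dichotomize_allred(allred_total(ihc$intensity, ihc$proportion))
    cmp <- compare_pfs(grp, ihc$pfs_weeks)
    report$stages$allred <<- list(n = nrow(ihc),
                                  n_high = sum(grp == "High"), n_low = sum(grp == "Low"),
                                  U = cmp$U, p = cmp$p, medians = as.list(cmp$medians))
  })

  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("report written to ", file.path(cfg$outdir, "report.json"))
  invisible(report)
}

#' Validate a pipeline report against the bundled schema
#'
#' Light structural validation: checks that the report carries the required
#' top-level fields and, for every stage present, the fields the bundled
#' schema (`inst/schema/report-schema.json`) requires of it.
#'
#' @param report a report list (as returned by [run_pipeline()]) or path to
#'   a `report.json`.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::fromJSON(report, simplifyVector = FALSE)
  schema <- jsonlite::fromJSON(system.file("schema", "report-schema.json",
                                           package = "rab5atools"),
                               simplifyVector = FALSE)
  for (f in unlist(schema$required)) {
    if (is.null(report[[f]])) stop_input("report lacks required field: ", f)
  }
  for (stage in names(schema$stages)) {
    if (is.null(report$stages[[stage]])) next
    for (f in unlist(schema$stages[[stage]])) {
      if (is.null(report$stages[[stage]][[f]]))
        stop_input("stage '", stage, "' lacks required field: ", f)
    }
  }
  invisible(TRUE)
}
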