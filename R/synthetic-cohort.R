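#' Simulation configuration for a synthetic trial cohort
#'
#' Bundles the parameters of the generating model used by
#' [generate_trial_cohort()]. The defaults reproduce the structure of the
#' neoadjuvant trial analysed throughout this package: a T-DM1 + pertuzumab
#' arm of 52 patients against a trastuzumab + paclitaxel control of 31, plus
#' an auxiliary trastuzumab + paclitaxel + pertuzumab arm of 44; an
#' arm-specific biomarker location shift (control-arm RAB5A runs higher than
#' the experimental arm); and a binary pathologic complete response (pCR)
#' drawn from a logistic model with a biomarker-by-treatment interaction and
#' a hormone-receptor covariate.
#'
#' The generating linear predictor for patient \eqn{i} is
#' \deqn{\eta_i = \beta_0 + \beta_{arm} T_i + \beta_{marker} x_i +
#'       \beta_{int} g(x_i) T_i + \beta_{HR} H_i,}
#' where \eqn{T_i} indicates the experimental (TDM1P) arm, \eqn{x_i} is the
#' designated biomarker on its normalized log-like scale, \eqn{H_i} indicates
#' hormone-receptor-negative status, and \eqn{g(x) = x} for
#' `interaction_form = "linear"` or \eqn{g(x) = 1[x \ge breakpoint]} for
#' `interaction_form = "step"`. The step form exists so that threshold-
#' recovery experiments have a true dichotomizing breakpoint to find.
#'
#' Default biomarker means (10.35 experimental / 11.0 control, SD 0.8) place
#' 23% of the experimental arm and 6% of the control arm below the reference
#' threshold of 9.76, matching the observed low-group fractions; default
#' coefficients give marginal pCR rates near 30/52 and 8/31.
#'
#' @param n_per_arm named integer vector of arm sizes (names among
#'   `"TDM1P"`, `"TH"`, `"THP"`; zero drops an arm).
#' @param biomarker_mean named numeric vector, per-arm mean of the designated
#'   biomarker on the normalized expression scale.
#' @param biomarker_sd positive scalar, common biomarker SD.
#' @param beta0,beta_arm,beta_marker,beta_interaction,beta_hr logit-scale
#'   coefficients of the generating model.
#' @param hr_neg_fraction probability a patient is hormone-receptor negative.
#' @param interaction_form `"linear"` (interaction in the continuous
#'   biomarker) or `"step"` (interaction in the indicator `x >= breakpoint`).
#' @param breakpoint threshold used when `interaction_form = "step"`.
#' @param seed integer RNG seed; the whole cohort is deterministic given it.
#' @return an object of class `cohort_sim_config` (a validated list).
#' @seealso [generate_trial_cohort()]
#' @export
cohort_sim_config <- function(n_per_arm = c(TDM1P = 52, TH = 31, THP = 44),
                              biomarker_mean = c(TDM1P = 10.35, TH = 11.0, THP = 10.5),
                              biomarker_sd = 0.8,
                              beta0 = -1.05,
                              beta_arm = -9.0,
                              beta_marker = 0,
                              beta_interaction = 1.0,
                              beta_hr = 0.4,
                              hr_neg_fraction = 0.35,
                              interaction_form = c("linear", "step"),
                              breakpoint = NULL,
                              seed = 1L) {
  interaction_form <- match.arg(interaction_form)
  if (is.null(names(n_per_arm)) || !all(names(n_per_arm) %in% ARM_LEVELS))
    stop_input("'n_per_arm' must be named with arms among ", paste(ARM_LEVELS, collapse = ", "))
  if (any(n_per_arm < 0) || any(n_per_arm != round(n_per_arm)))
    stop_input("arm sizes must be non-negative integers")
  if (!is.numeric(biomarker_sd) || biomarker_sd <= 0)
    stop_input("'biomarker_sd' must be > 0")
  if (hr_neg_fraction < 0 || hr_neg_fraction > 1)
    stop_input("'hr_neg_fraction' must lie in [0, 1]")
  arms <- names(n_per_arm)[n_per_arm > 0]
  if (!all(arms %in% names(biomarker_mean)))
    stop_input("'biomarker_mean' must name every arm with positive size")
  if (interaction_form == "step" && is.null(breakpoint))
    stop_input("'breakpoint' is required when interaction_form = \"step\"")
  for (b in c(beta0, beta_arm, beta_marker, beta_interaction, beta_hr))
    if (!is.numeric(b) || length(b) != 1L || !is.finite(b))
      stop_input("model coefficients must be finite scalars")
  structure(
    list(n_per_arm = n_per_arm, biomarker_mean = biomarker_mean,
         biomarker_sd = biomarker_sd, beta0 = beta0, beta_arm = beta_arm,
         beta_marker = beta_marker, beta_interaction = beta_interaction,
         beta_hr = beta_hr, hr_neg_fraction = hr_neg_fraction,
         interaction_form = interaction_form, breakpoint = breakpoint,
         seed = as.integer(seed)),
    class = "cohort_sim_config")
}

#' Read a cohort simulation configuration from YAML or JSON
#'
#' The file may supply any subset of the [cohort_sim_config()] arguments;
#' unnamed fields fall back to the defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `cohort_sim_config`.
#' @export
cohort_sim_config_from_file <- function(path) {
  cfg <- read_config_file(path)
  known <- names(formals(cohort_sim_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop_input("unknown config fields: ", paste(bad, collapse = ", "))
  for (f in c("n_per_arm", "biomarker_mean"))
    if (!is.null(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])
  do.call(cohort_sim_config, cfg)
}

#' Generate a synthetic trial cohort
#'
#' Draws a patient-level cohort with the structure described in
#' [cohort_sim_config()]: per-arm Gaussian biomarker expression, Bernoulli
#' hormone-receptor status, and pCR generated from the logistic
#' biomarker-by-treatment interaction model. The three nuisance markers
#' (RAB4A, RAB11A and ERBB2) are drawn independently of outcome. Platform
#' labels mirror the trial's assay history: all experimental- and
#' auxiliary-arm samples on the newer array, the control arm split roughly
#' 22:9 between the older and newer designs.
#'
#' @param config a [cohort_sim_config()].
#' @param marker name of the designated (outcome-linked) biomarker column;
#'   default `"RAB5A"`.
#' @return a `data.frame` of class `trial_cohort` with columns
#'   `patient_id`, `arm`, `hr_status`, `pcr` (logical), `platform`,
#'   `RAB4A`, `RAB5A`, `RAB11A`, `ERBB2`, and a `provenance` attribute.
#' @examples
#' cohort <- generate_trial_cohort(cohort_sim_config(seed = 7))
#' table(cohort$arm)
#' @export
generate_trial_cohort <- function(config = cohort_sim_config(), marker = "RAB5A") {
  stopifnot(inherits(config, "cohort_sim_config"))
  if (!marker %in% MARKERS) stop_input("'marker' must be one of ", paste(MARKERS, collapse = ", "))
  arms <- names(config$n_per_arm)[config$n_per_arm > 0]
  arms <- ARM_LEVELS[ARM_LEVELS %in% arms]  # fixed generation order
  withr::with_seed(config$seed, {
    pieces <- lapply(arms, function(a) {
      n <- config$n_per_arm[[a]]
      x <- stats::rnorm(n, config$biomarker_mean[[a]], config$biomarker_sd)
      hr_neg <- stats::rbinom(n, 1L, config$hr_neg_fraction)
      trt <- as.numeric(a == "TDM1P")
      g <- if (config$interaction_form == "linear") x else as.numeric(x >= config$breakpoint)
      eta <- config$beta0 + config$beta_arm * trt + config$beta_marker * x +
        config$beta_interaction * g * trt + config$beta_hr * hr_neg
      pcr <- stats::rbinom(n, 1L, invlogit(eta)) == 1L
      # nuisance markers: independent of outcome by construction
      nuis <- matrix(stats::rnorm(3L * n, mean = rep(c(10, 10, 11), each = n), sd = 1),
                     nrow = n, dimnames = list(NULL, c("RAB4A", "RAB11A", "ERBB2")))
      platform <- if (a == "TH") {
        n_old <- round(22 / 31 * n)
        c(rep("P15746", n_old), rep("P32627", n - n_old))
      } else rep("P32627", n)
      df <- data.frame(
        patient_id = sprintf("%s-%03d", a, seq_len(n)),
        arm = a,
        hr_status = ifelse(hr_neg == 1L, "HRneg", "HRpos"),
        pcr = pcr,
        platform = platform,
        stringsAsFactors = FALSE)
      df[[marker]] <- x
      for (m in setdiff(MARKERS, marker)) df[[m]] <- nuis[, m]
      df
    })
    cohort <- do.call(rbind, pieces)
  })
  cohort <- cohort[, c("patient_id", "arm", "hr_status", "pcr", "platform", MARKERS)]
  cohort$arm <- factor(cohort$arm, levels = ARM_LEVELS[ARM_LEVELS %in% arms])
  cohort$hr_status <- factor(cohort$hr_status, levels = HR_LEVELS)
  cohort$platform <- factor(cohort$platform, levels = PLATFORM_LEVELS)
  rownames(cohort) <- NULL
  attr(cohort, "provenance") <- sprintf("synthetic cohort (seed %d)", config$seed)
  class(cohort) <- c("trial_cohort", "data.frame")
  cohort
}

#' Generate a synthetic cell-line viability panel
#'
#' Emulates an in-vitro panel in which drug sensitivity, measured as
#' 1/IC50, is linear in the relative expression of a designated marker:
#' each line receives a marker value in \[0, 1\] (scaled so the
#' highest-expressing line is 1, as in densitometric quantification
#' relative to the top expressor), a true IC50 defined by
#' `1/IC50 = slope * marker + intercept`, and replicate viability readings
#' from the sigmoid dose-response model `a / (1 + exp(-(x - x0)/b))` on
#' `x = log10(concentration)` plus Gaussian noise.
#'
#' @param n_lines number of cell lines (>= 2).
#' @param slope,intercept coefficients of the sensitivity line; every line's
#'   `slope * marker + intercept` must be positive or the IC50 is undefined.
#' @param noise_sd SD of additive Gaussian viability noise (0 gives exact
#'   sigmoid readings).
#' @param seed integer RNG seed.
#' @param n_replicates independent experiments per line (default 3).
#' @param concentrations dose grid in ug/ml; defaults to ten log-spaced
#'   doses spanning 1e-4 to 10.
#' @param marker marker name used in the output; default `"RAB5A"`.
#' @param sigmoid_b true slope-scale parameter of the generating sigmoid
#'   (negative: viability falls with dose).
#' @return an object of class `cellline_panel`: a list with `lines`
#'   (`name`, marker column, `true_ic50`) and `viability`
#'   (`cell_line`, `drug`, `concentration`, `replicate`, `viability`).
#' @export
generate_cellline_panel <- function(n_lines = 5, slope = 200, intercept = 1,
                                    noise_sd = 0.05, seed = 1L,
                                    n_replicates = 3,
                                    concentrations = 10^seq(-4, 1, length.out = 10),
                                    marker = "RAB5A", sigmoid_b = -0.5) {
  if (!is_count(n_lines) || n_lines < 2) stop_input("'n_lines' must be an integer >= 2")
  if (any(concentrations <= 0)) stop_input("concentrations must be > 0")
  if (noise_sd < 0) stop_input("'noise_sd' must be >= 0")
  withr::with_seed(as.integer(seed), {
    expr <- stats::runif(n_lines, 0.05, 1)
    expr <- expr / max(expr)  # relative to the highest-expressing line
    inv_ic50 <- slope * expr + intercept
    if (any(inv_ic50 <= 0))
      stop_input("slope * marker + intercept must be positive for every line (IC50 undefined)")
    ic50 <- 1 / inv_ic50
    lines <- data.frame(name = sprintf("CL%02d", seq_len(n_lines)), stringsAsFactors = FALSE)
    lines[[marker]] <- expr
    lines$true_ic50 <- ic50
    x <- log10(concentrations)
    viab <- do.call(rbind, lapply(seq_len(n_lines), function(i) {
      x0 <- log10(ic50[i])  # a = 1, so absolute half-max sits at x0
      mu <- 1 / (1 + exp(-(x - x0) / sigmoid_b))
      do.call(rbind, lapply(seq_len(n_replicates), function(r) {
        data.frame(cell_line = lines$name[i], drug = "T-DM1",
                   concentration = concentrations, replicate = r,
                   viability = pmax(0, mu + stats::rnorm(length(x), 0, noise_sd)),
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  rownames(viab) <- NULL
  structure(list(lines = lines, viability = viab, marker = marker),
            class = "cellline_panel")
}

#' Generate a synthetic IHC cohort with Allred scores and PFS
#'
#' Samples Allred intensity (0-3) and proportion (0-5) components over the
#' valid grid (a tumor with no stained cells scores 0 on both; any staining
#' implies intensity >= 1, so a total of 1 is unreachable) and draws
#' progression-free survival so that patients with total score 7-8 are
#' shifted upward by `effect` weeks. The default size matches the 19-patient
#' biopsy subset the IHC analysis was developed on.
#'
#' @param n cohort size (>= 2).
#' @param effect upward PFS shift (weeks) for total Allred score 7-8;
#'   default 40 separates the groups around the 50-week landmark.
#' @param seed integer RNG seed.
#' @return a `data.frame` with `patient_id`, `intensity`, `proportion`,
#'   `total` (Allred sum), `pfs_weeks` and `status`
#'   (`"progressed"` or `"stopped_or_lost"`).
#' @export
generate_ihc_cohort <- function(n = 19, effect = 40, seed = 1L) {
  if (!is_count(n) || n < 2) stop_input("'n' must be an integer >= 2")
  withr::with_seed(as.integer(seed), {
    negative <- stats::rbinom(n, 1L, 0.15) == 1L
    intensity <- ifelse(negative, 0L, sample(1:3, n, replace = TRUE, prob = c(0.2, 0.3, 0.5)))
    proportion <- ifelse(negative, 0L,
                         sample(1:5, n, replace = TRUE, prob = c(0.1, 0.1, 0.15, 0.25, 0.4)))
    total <- intensity + proportion
    pfs <- stats::rgamma(n, shape = 4, scale = 6) + effect * (total >= 7)
    pfs <- pmax(pfs, 1)
    status <- ifelse(pfs >= 50 & stats::runif(n) < 0.3, "stopped_or_lost", "progressed")
  })
  data.frame(patient_id = sprintf("K-%02d", seq_len(n)),
             intensity = as.integer(intensity), proportion = as.integer(proportion),
             total = as.integer(total), pfs_weeks = pfs, status = status,
             stringsAsFactors = FALSE)
}
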