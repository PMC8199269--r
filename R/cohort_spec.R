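#' Default covariate prevalences for the synthetic elderly cohort
#'
#' Whole-population prevalences of the binary risk factors used by
#' [generate_cohort()]. History flags (`mi`, `chd`, ...) are generated
#' directly as booleans; the condition flags (`dm`, `ha`, `ckd`, `obesity`,
#' `ntprobnp_high`, `hscrp_high`) are realised through laboratory values and
#' medication flags so that guideline phenotyping ([phenotype_cohort()])
#' recovers them.
#'
#' @return Named numeric vector of probabilities.
#' @export
default_covariate_prevalences <- function() {
  c(
    male              = 0.509,
    mi                = 0.148,
    chd               = 0.221,
    thyroid           = 0.139,
    pulmonary         = 0.120,
    thromboembolism   = 0.080,
    lead              = 0.138,
    ics_tia           = 0.121,
    pci_cabg          = 0.122,
    dm                = 0.292,
    heart_failure     = 0.223,
    ha                = 0.807,
    ckd               = 0.333,
    physical_activity = 0.429,
    obesity           = 0.306,
    hscrp_high        = 0.187,
    ntprobnp_high     = 0.759
  )
}

#' Default effect sizes (log odds ratios) for the outcome models
#'
#' Adjusted odds ratios for overall AF and for silent AF in an elderly
#' general-population screening cohort. Age enters per 5 years above 65
#' (`age_per5`); all other terms are the binary factors of
#' [default_covariate_prevalences()].
#'
#' @param outcome `"af"` for overall (symptomatic or silent) AF, `"saf"` for
#'   silent AF.
#' @return Named numeric vector of log odds ratios.
#' @export
default_log_ors <- function(outcome = c("af", "saf")) {
  outcome <- match.arg(outcome)
  or <- if (outcome == "af") {
    c(
      age_per5 = 1.26, male = 2.05, mi = 0.96, chd = 1.30, thyroid = 1.44,
      pulmonary = 0.87, thromboembolism = 1.28, lead = 0.96, ics_tia = 1.28,
      pci_cabg = 0.43, dm = 1.39, heart_failure = 2.98, ha = 1.29,
      ckd = 1.25, physical_activity = 1.03, obesity = 1.43,
      hscrp_high = 0.89, ntprobnp_high = 1.95
    )
  } else {
    c(
      age_per5 = 1.36, male = 2.58, mi = 0.68, chd = 1.10, thyroid = 1.41,
      pulmonary = 0.67, thromboembolism = 1.41, lead = 1.11, ics_tia = 1.59,
      pci_cabg = 0.64, dm = 1.48, heart_failure = 2.06, ha = 0.85,
      ckd = 1.39, physical_activity = 1.02, obesity = 1.21,
      hscrp_high = 0.83, ntprobnp_high = 2.37
    )
  }
  log(or)
}

#' Default laboratory-value generation parameters
#'
#' Conditional distributions used to realise each latent condition flag as
#' laboratory values and medication flags, chosen so the guideline thresholds
#' reproduce the flag. Stored on the spec (not hard-coded) so alternative
#' assay distributions can be supplied.
#'
#' @return Named list of distribution parameters.
#' @export
default_lab_distributions <- function() {
  list(
    # hypertension: treated fraction among hypertensives; BP means/SDs (mmHg)
    ha = list(treated_frac = 0.85,
              sbp_treated = c(mean = 135, sd = 12),
              dbp_treated = c(mean = 80, sd = 8),
              sbp_untreated = c(mean = 152, sd = 10),  # truncated >= 140
              dbp_untreated = c(mean = 85, sd = 8),
              sbp_normal = c(mean = 125, sd = 8),      # truncated < 140
              dbp_normal = c(mean = 74, sd = 7)),      # truncated < 90
    # diabetes: treated fraction; HbA1c (%) mixture components
    dm = list(treated_frac = 0.75,
              hba1c_treated = c(mean = 7.0, sd = 0.9),
              hba1c_untreated = c(mean = 6.9, sd = 0.4),  # truncated >= 6.5
              hba1c_normal = c(mean = 5.7, sd = 0.35)),   # truncated < 6.5
    # CKD: branch mix (low eGFR only / albuminuria only / both) and the
    # target eGFR (mL/min/1.73 m^2) and ACR (mg/g) ranges per branch;
    # creatinine is obtained by inverting the CKD-EPI equation.
    ckd = list(branch_probs = c(egfr = 0.55, acr = 0.25, both = 0.20),
               egfr_low = c(20, 59.5), egfr_ok = c(60.5, 105),
               acr_low = c(1, 29), acr_high_logsd = 0.9),
    obesity = list(bmi_obese_shape = 2, bmi_obese_scale = 2,   # 30 + gamma
                   bmi_normal = c(mean = 26.5, sd = 3)),       # truncated < 30
    ntprobnp = list(high_logsd = 0.9, low_range = c(10, 124.9)),  # pg/mL
    hscrp = list(high_logsd = 0.7, low_range = c(0.1, 4.99))      # mg/L
  )
}

#' Specification of a synthetic screening cohort
#'
#' Bundles every generative parameter for [generate_cohort()]: demographics,
#' binary covariate prevalences, effect sizes for the AF and silent-AF
#' outcome models, target outcome prevalences, laboratory distributions,
#' ECG-monitoring parameters and the seed.
#'
#' @param n_subjects Number of subjects (default 3014).
#' @param age_mean,age_sd Age distribution in years before truncation
#'   (defaults 77.5 and 7.9).
#' @param age_min Lower truncation bound in years (default 65; study entry
#'   criterion).
#' @param covariate_prevalences Named probabilities for the binary factors;
#'   see [default_covariate_prevalences()].
#' @param af_log_ors,saf_log_ors Named log odds ratios for the overall-AF and
#'   silent-AF models; see [default_log_ors()]. `age_per5` applies to
#'   `(age - 65) / 5`.
#' @param target_af_prevalence,target_saf_prevalence Overall AF (default
#'   0.226) and silent-AF (default 0.093) prevalences the calibrated
#'   intercepts aim at.
#' @param lab_distributions See [default_lab_distributions()].
#' @param monitoring_days_target_median Median effective ECG monitoring time
#'   in days (default 23 d 10 h 26 min).
#' @param monitoring_days_min Lower truncation for monitoring time in days
#'   (default 12 minutes).
#' @param monitoring_logsd Log-scale SD of the lognormal monitoring time.
#' @param sub30_fraction Fraction of AF-negative subjects that receive only
#'   sub-30-second episodes, to exercise the episode-duration filter
#'   (default 0.15).
#' @param covariate_correlation Optional named, symmetric correlation matrix
#'   over (a subset of) the binary factors; when supplied the flags are drawn
#'   from a Gaussian copula with these latent correlations instead of
#'   independently. Default `NULL` (independent factors).
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [calibrate_intercept()]
#' @export
cohort_spec <- function(n_subjects = 3014,
                        age_mean = 77.5,
                        age_sd = 7.9,
                        age_min = 65,
                        covariate_prevalences = default_covariate_prevalences(),
                        af_log_ors = default_log_ors("af"),
                        saf_log_ors = default_log_ors("saf"),
                        target_af_prevalence = 0.226,
                        target_saf_prevalence = 0.093,
                        lab_distributions = default_lab_distributions(),
                        monitoring_days_target_median = 23 + (10 * 60 + 26) / 1440,
                        monitoring_days_min = 12 / 1440,
                        monitoring_logsd = 0.6,
                        sub30_fraction = 0.15,
                        covariate_correlation = NULL,
                        seed = 1L) {
  spec <- structure(
    list(
      n_subjects = as.integer(n_subjects),
      age_mean = age_mean, age_sd = age_sd, age_min = age_min,
      covariate_prevalences = covariate_prevalences,
      af_log_ors = af_log_ors, saf_log_ors = saf_log_ors,
      target_af_prevalence = target_af_prevalence,
      target_saf_prevalence = target_saf_prevalence,
      lab_distributions = lab_distributions,
      monitoring_days_target_median = monitoring_days_target_median,
      monitoring_days_min = monitoring_days_min,
      monitoring_logsd = monitoring_logsd,
      sub30_fraction = sub30_fraction,
      covariate_correlation = covariate_correlation,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  p <- spec$covariate_prevalences
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    stopf("covariate_prevalences must be a named vector")
  }
  if (any(p < 0 | p > 1)) stopf("covariate prevalences must lie in [0, 1]")
  for (t in c("target_af_prevalence", "target_saf_prevalence", "sub30_fraction")) {
    if (spec[[t]] < 0 || spec[[t]] > 1) stopf("%s must lie in [0, 1]", t)
  }
  if (spec$target_saf_prevalence >= spec$target_af_prevalence) {
    stopf("target_saf_prevalence must be below target_af_prevalence")
  }
  if (spec$n_subjects < 1) stopf("n_subjects must be at least 1")
  if (spec$age_min > spec$age_mean) stopf("age_min must not exceed age_mean")
  for (m in c("af_log_ors", "saf_log_ors")) {
    covs <- setdiff(names(spec[[m]]), "age_per5")
    missing <- setdiff(covs, names(p))
    if (length(missing)) {
      stopf("%s names a factor with no generation rule: %s",
            m, paste(missing, collapse = ", "))
    }
  }
  if (!is.null(spec$covariate_correlation)) {
    cc <- spec$covariate_correlation
    if (!isSymmetric(unname(cc)) ||
        is.null(rownames(cc)) ||
        !all(rownames(cc) %in% names(p))) {
      stopf("covariate_correlation must be a symmetric matrix named after covariates")
    }
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  subjects: %d, age ~ N(%.1f, %.1f) truncated at %.0f y\n",
              x$n_subjects, x$age_mean, x$age_sd, x$age_min))
  cat(sprintf("  target prevalence: AF %.1f%%, silent AF %.1f%%\n",
              100 * x$target_af_prevalence, 100 * x$target_saf_prevalence))
  cat(sprintf("  binary factors: %d, seed: %d\n",
              length(x$covariate_prevalences), x$seed))
  invisible(x)
}
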