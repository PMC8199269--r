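#' Guideline thresholds for clinical phenotyping
#'
#' Threshold set used by [phenotype_cohort()]. Defaults follow the ESC/ADA/
#' KDIGO criteria current at the time of large elderly AF-screening studies:
#' AF requires an ECG episode strictly longer than 30 s; hypertension at mean
#' BP >= 140/90 mmHg or antihypertensive treatment; diabetes at
#' HbA1c >= 6.5% or glucose-lowering treatment; CKD at eGFR < 60 or
#' ACR >= 30 mg/g; obesity at BMI >= 30; NT-proBNP and hs-CRP flags use
#' strict `>` at 125 pg/mL and 5 mg/L. `age_score_cut` dichotomises age for
#' the risk score (>= 75 years). `race_coef` is the CKD-EPI race coefficient,
#' fixed at 1 for a European population sample but exposed for generality.
#'
#' @param af_min_episode_s,sbp_mmHg,dbp_mmHg,hba1c_pct,egfr_ckd,acr_mg_g,bmi_obese,ntprobnp_pg_ml,hscrp_mg_l,age_score_cut,race_coef
#'   Numeric thresholds; see Description.
#' @return An object of class `phenotype_thresholds`.
#' @export
phenotype_thresholds <- function(af_min_episode_s = 30,
                                 sbp_mmHg = 140,
                                 dbp_mmHg = 90,
                                 hba1c_pct = 6.5,
                                 egfr_ckd = 60,
                                 acr_mg_g = 30,
                                 bmi_obese = 30,
                                 ntprobnp_pg_ml = 125,
                                 hscrp_mg_l = 5,
                                 age_score_cut = 75,
                                 race_coef = 1) {
  thr <- list(
    af_min_episode_s = af_min_episode_s, sbp_mmHg = sbp_mmHg,
    dbp_mmHg = dbp_mmHg, hba1c_pct = hba1c_pct, egfr_ckd = egfr_ckd,
    acr_mg_g = acr_mg_g, bmi_obese = bmi_obese,
    ntprobnp_pg_ml = ntprobnp_pg_ml, hscrp_mg_l = hscrp_mg_l,
    age_score_cut = age_score_cut, race_coef = race_coef
  )
  if (any(unlist(thr) <= 0)) stopf("all phenotype thresholds must be positive")
  structure(thr, class = "phenotype_thresholds")
}

#' Estimated GFR by the CKD-EPI 2009 creatinine equation
#'
#' `141 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.209 * 0.993^age * 1.018[female]`
#' with knot `k` = 0.7 (female) / 0.9 (male) and exponent `a` = -0.329 /
#' -0.411. The race coefficient defaults to 1.
#'
#' @param creatinine Serum creatinine, mg/dL (positive).
#' @param age Age in years (>= 18).
#' @param sex `"male"`/`"female"` (vectorised, recycled).
#' @param race_coef Multiplicative race coefficient (default 1).
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' egfr_ckd_epi(1.2, 70, "male")    # ~60.9
#' egfr_ckd_epi(0.7, 65, "female")  # ~90.9
#' @export
egfr_ckd_epi <- function(creatinine, age, sex, race_coef = 1) {
  if (any(creatinine <= 0)) stopf("creatinine must be positive")
  if (any(age < 18)) stopf("the CKD-EPI 2009 equation applies to adults (age >= 18)")
  sex <- match.arg(tolower(as.character(sex)), c("male", "female"),
                   several.ok = TRUE)
  female <- rep_len(sex == "female", length(creatinine))
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  ratio <- creatinine / kappa
  141 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^(-1.209) *
    0.993^age * ifelse(female, 1.018, 1) * race_coef
}

#' Detect AF from an ECG episode list
#'
#' A subject is AF-positive if and only if at least one confirmed episode
#' lasts strictly longer than the minimum duration (30 s by guideline).
#' Durations are compared exactly as stored; an episode of exactly 30 s does
#' not qualify.
#'
#' @param episodes A `data.frame` with a `duration` column in seconds (one
#'   row per episode), or a numeric vector of durations. An empty list is
#'   AF-negative.
#' @param thr A [phenotype_thresholds()].
#' @return Logical scalar.
#' @examples
#' detect_af(numeric(0))        # FALSE
#' detect_af(c(25, 30))         # FALSE: 30 s does not exceed 30 s
#' detect_af(c(29, 31))         # TRUE: one qualifying episode suffices
#' @export
detect_af <- function(episodes, thr = phenotype_thresholds()) {
  dur <- if (is.data.frame(episodes)) episodes$duration else episodes
  if (is.null(dur) || !length(dur)) return(FALSE)
  if (any(dur <= 0)) stopf("episode durations must be positive")
  any(dur > thr$af_min_episode_s)
}

#' Classify AF status as none, symptomatic or silent
#'
#' Silent AF is detected AF in an asymptomatic subject; symptomatic AF is
#' detected AF with symptoms; anything else (including symptoms without
#' detected AF) is no-AF.
#'
#' @param af_detected,symptomatic Logical vectors (recycled to a common
#'   length).
#' @return Factor with levels `no_af`, `symptomatic_af`, `silent_af`.
#' @export
classify_saf <- function(af_detected, symptomatic) {
  n <- max(length(af_detected), length(symptomatic))
  af_detected <- rep_len(af_detected, n)
  symptomatic <- rep_len(symptomatic, n)
  out <- ifelse(af_detected & !symptomatic, "silent_af",
                ifelse(af_detected & symptomatic, "symptomatic_af", "no_af"))
  factor(out, levels = c("no_af", "symptomatic_af", "silent_af"))
}

phenotype_fields <- c("age", "sex", "sbp", "dbp", "antihypertensive",
                      "hba1c", "glucose_lowering", "creatinine", "acr",
                      "bmi", "ntprobnp", "hscrp", "symptomatic")

#' Derive guideline phenotypes and AF status for a cohort
#'
#' Applies the clinical definitions to every subject: hypertension (`ha`) at
#' mean SBP >= 140 or mean DBP >= 90 or antihypertensive treatment; diabetes
#' (`dm`) at HbA1c >= 6.5% or glucose-lowering treatment; CKD at CKD-EPI
#' eGFR < 60 mL/min/1.73 m^2 or ACR >= 30 mg/g; obesity at BMI >= 30;
#' elevated NT-proBNP (> 125 pg/mL) and hs-CRP (> 5 mg/L) use strict
#' inequalities; `age75` dichotomises age at the score cut (>= 75 y).
#' AF status comes from the episode list (> 30 s rule) combined with the
#' symptom flag via [classify_saf()].
#'
#' Subjects with a missing required field are excluded (complete-case) and
#' logged in the `"exclusions"` attribute (`id`, `field`).
#'
#' @param cohort Cohort `data.frame` as produced by [generate_cohort()] or
#'   [read_cohort()].
#' @param thr A [phenotype_thresholds()].
#' @return The cohort with added columns `egfr`, `ha`, `dm`, `ckd`,
#'   `obesity`, `ntprobnp_high`, `hscrp_high`, `male`, `age75`,
#'   `af_detected`, `af_status`, `saf`, plus the `"exclusions"` attribute.
#' @export
phenotype_cohort <- function(cohort, thr = phenotype_thresholds()) {
  missing_cols <- setdiff(phenotype_fields, names(cohort))
  if (length(missing_cols)) {
    stopf("cohort lacks required columns: %s", paste(missing_cols, collapse = ", "))
  }
  bad <- lapply(phenotype_fields, function(f) which(is.na(cohort[[f]])))
  names(bad) <- phenotype_fields
  excl_idx <- sort(unique(unlist(bad)))
  exclusions <- data.frame(
    id = rep(cohort$id[unlist(bad)] %||% as.character(unlist(bad)),
             times = 1),
    field = rep(names(bad), lengths(bad)),
    stringsAsFactors = FALSE
  )
  if (length(excl_idx)) cohort <- cohort[-excl_idx, , drop = FALSE]

  cohort$egfr <- egfr_ckd_epi(cohort$creatinine, cohort$age, cohort$sex,
                              race_coef = thr$race_coef)
  cohort$male <- cohort$sex == "male"
  cohort$ha <- cohort$sbp >= thr$sbp_mmHg | cohort$dbp >= thr$dbp_mmHg |
    cohort$antihypertensive
  cohort$dm <- cohort$hba1c >= thr$hba1c_pct | cohort$glucose_lowering
  cohort$ckd <- cohort$egfr < thr$egfr_ckd | cohort$acr >= thr$acr_mg_g
  cohort$obesity <- cohort$bmi >= thr$bmi_obese
  cohort$ntprobnp_high <- cohort$ntprobnp > thr$ntprobnp_pg_ml
  cohort$hscrp_high <- cohort$hscrp > thr$hscrp_mg_l
  cohort$age75 <- cohort$age >= thr$age_score_cut
  cohort$af_detected <- if (is.null(cohort$episodes)) {
    rep(FALSE, nrow(cohort))
  } else {
    vapply(cohort$episodes, detect_af, logical(1), thr = thr)
  }
  cohort$af_status <- classify_saf(cohort$af_detected, cohort$symptomatic)
  cohort$saf <- cohort$af_status == "silent_af"
  attr(cohort, "exclusions") <- exclusions
  cohort
}
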