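#' Calibrate a logistic-model intercept to a target prevalence
#'
#' Finds the intercept `b0` such that the mean of `plogis(b0 + eta)` over the
#' supplied linear predictors equals the target prevalence, by monotone
#' bisection. Used to anchor the synthetic outcome models at the published
#' prevalences (22.6% overall AF, 9.3% silent AF).
#'
#' @param eta Numeric vector of linear predictors `x %*% beta` (without
#'   intercept), one per subject.
#' @param target Target prevalence in (0, 1).
#' @param tol Convergence tolerance on the achieved prevalence
#'   (default 1e-6, well inside the 0.002 contract).
#' @return The intercept, a single numeric value.
#' @examples
#' calibrate_intercept(rep(0, 100), 0.5)            # 0
#' calibrate_intercept(rep(0, 100), 0.226)          # log(0.226 / 0.774)
#' @export
calibrate_intercept <- function(eta, target, tol = 1e-6) {
  if (!is.numeric(target) || length(target) != 1 || target <= 0 || target >= 1) {
    stopf("target prevalence must be a single value in (0, 1)")
  }
  if (!length(eta) || any(!is.finite(eta))) {
    stopf("linear predictors must be finite and non-empty")
  }
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0) {
    stopf("target prevalence %.4f is not achievable for these predictors", target)
  }
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Invert the CKD-EPI 2009 equation: serum creatinine (mg/dL) giving the
# requested eGFR at this age/sex. Piecewise monotone, so closed form.
invert_ckd_epi <- function(egfr, age, female, race_coef = 1) {
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  base <- 141 * 0.993^age * ifelse(female, 1.018, 1) * race_coef
  ratio <- ifelse(egfr < base,
                  (egfr / base)^(-1 / 1.209),  # creatinine above the knot
                  (egfr / base)^(1 / alpha))   # at or below the knot
  kappa * ratio
}

# Draw the binary covariates: independent Bernoulli by default, or a Gaussian
# copula when spec$covariate_correlation names a subset of factors.
draw_covariates <- function(spec, n) {
  p <- spec$covariate_prevalences
  X <- matrix(0L, n, length(p), dimnames = list(NULL, names(p)))
  corr <- spec$covariate_correlation
  if (!is.null(corr)) {
    vars <- rownames(corr)
    L <- chol(corr)
    Z <- matrix(stats::rnorm(n * length(vars)), n) %*% L
    for (j in seq_along(vars)) {
      X[, vars[j]] <- as.integer(Z[, j] < stats::qnorm(p[vars[j]]))
    }
    rest <- setdiff(names(p), vars)
  } else {
    rest <- names(p)
  }
  for (v in rest) X[, v] <- stats::rbinom(n, 1, p[v])
  X
}

# Realise latent condition flags as labs + medication flags so that the
# guideline thresholds in phenotype_cohort() reproduce each flag exactly.
draw_labs <- function(X, age, female, lab) {
  n <- length(age)
  ha <- X[, "ha"] == 1
  treated_ha <- ha & stats::runif(n) < lab$ha$treated_frac
  sbp <- dbp <- numeric(n)
  untreated_ha <- ha & !treated_ha
  sbp[treated_ha] <- stats::rnorm(sum(treated_ha), lab$ha$sbp_treated["mean"],
                                  lab$ha$sbp_treated["sd"])
  dbp[treated_ha] <- stats::rnorm(sum(treated_ha), lab$ha$dbp_treated["mean"],
                                  lab$ha$dbp_treated["sd"])
  sbp[untreated_ha] <- rnorm_trunc(sum(untreated_ha),
                                   lab$ha$sbp_untreated["mean"],
                                   lab$ha$sbp_untreated["sd"], lower = 140)
  dbp[untreated_ha] <- stats::rnorm(sum(untreated_ha),
                                    lab$ha$dbp_untreated["mean"],
                                    lab$ha$dbp_untreated["sd"])
  sbp[!ha] <- rnorm_trunc(sum(!ha), lab$ha$sbp_normal["mean"],
                          lab$ha$sbp_normal["sd"], upper = 139.9)
  dbp[!ha] <- rnorm_trunc(sum(!ha), lab$ha$dbp_normal["mean"],
                          lab$ha$dbp_normal["sd"], upper = 89.9)
  sbp <- pmax(sbp, 70); dbp <- pmax(dbp, 40)

  dm <- X[, "dm"] == 1
  treated_dm <- dm & stats::runif(n) < lab$dm$treated_frac
  hba1c <- numeric(n)
  hba1c[treated_dm] <- pmax(stats::rnorm(sum(treated_dm),
                                         lab$dm$hba1c_treated["mean"],
                                         lab$dm$hba1c_treated["sd"]), 4.5)
  untreated_dm <- dm & !treated_dm
  hba1c[untreated_dm] <- rnorm_trunc(sum(untreated_dm),
                                     lab$dm$hba1c_untreated["mean"],
                                     lab$dm$hba1c_untreated["sd"], lower = 6.5)
  hba1c[!dm] <- rnorm_trunc(sum(!dm), lab$dm$hba1c_normal["mean"],
                            lab$dm$hba1c_normal["sd"],
                            lower = 4.0, upper = 6.49)

  ckd <- X[, "ckd"] == 1
  egfr_target <- stats::runif(n, lab$ckd$egfr_ok[1], lab$ckd$egfr_ok[2])
  acr <- stats::runif(n, lab$ckd$acr_low[1], lab$ckd$acr_low[2])
  if (any(ckd)) {
    m <- sum(ckd)
    u <- stats::runif(m)
    bp <- cumsum(lab$ckd$branch_probs / sum(lab$ckd$branch_probs))
    low_egfr <- u < bp["egfr"] | u >= bp["acr"]          # egfr-only or both
    high_acr <- u >= bp["egfr"]                          # acr-only or both
    eg <- stats::runif(m, lab$ckd$egfr_low[1], lab$ckd$egfr_low[2])
    egfr_target[ckd][low_egfr] <- eg[low_egfr]
    acr_hi <- 30 * exp(abs(stats::rnorm(m, 0, lab$ckd$acr_high_logsd)))
    acr[ckd][high_acr] <- acr_hi[high_acr]
  }
  creatinine <- invert_ckd_epi(egfr_target, age, female)

  obese <- X[, "obesity"] == 1
  bmi <- numeric(n)
  bmi[obese] <- 30 + stats::rgamma(sum(obese), lab$obesity$bmi_obese_shape,
                                   scale = lab$obesity$bmi_obese_scale)
  bmi[!obese] <- rnorm_trunc(sum(!obese), lab$obesity$bmi_normal["mean"],
                             lab$obesity$bmi_normal["sd"],
                             lower = 16, upper = 29.9)

  bnp_high <- X[, "ntprobnp_high"] == 1
  ntprobnp <- numeric(n)
  ntprobnp[bnp_high] <- 125 * exp(abs(stats::rnorm(sum(bnp_high), 0,
                                                   lab$ntprobnp$high_logsd)) + 1e-6)
  ntprobnp[!bnp_high] <- stats::runif(sum(!bnp_high),
                                      lab$ntprobnp$low_range[1],
                                      lab$ntprobnp$low_range[2])

  crp_high <- X[, "hscrp_high"] == 1
  hscrp <- numeric(n)
  hscrp[crp_high] <- 5 * exp(abs(stats::rnorm(sum(crp_high), 0,
                                              lab$hscrp$high_logsd)) + 1e-6)
  hscrp[!crp_high] <- stats::runif(sum(!crp_high),
                                   lab$hscrp$low_range[1],
                                   lab$hscrp$low_range[2])

  data.frame(
    sbp = sbp, dbp = dbp, antihypertensive = treated_ha,
    hba1c = hba1c, glucose_lowering = treated_dm,
    creatinine = creatinine, acr = acr,
    bmi = bmi, ntprobnp = ntprobnp, hscrp = hscrp
  )
}

# Linear predictor of a named log-OR map over the covariate matrix; age is
# coded per 5 years above the truncation bound.
linear_predictor <- function(log_ors, X, age, age_min) {
  eta <- numeric(nrow(X))
  if ("age_per5" %in% names(log_ors)) {
    eta <- eta + (age - age_min) / 5 * log_ors[["age_per5"]]
  }
  covs <- setdiff(names(log_ors), "age_per5")
  if (length(covs)) eta <- eta + drop(X[, covs, drop = FALSE] %*% log_ors[covs])
  eta
}

draw_episodes <- function(n_af, monitoring, long = TRUE) {
  lapply(seq_len(n_af), function(i) {
    k <- 1 + stats::rpois(1, if (long) 2 else 0.5)
    dur <- if (long) {
      30 + stats::rlnorm(k, meanlog = log(300), sdlog = 1.2)
    } else {
      stats::runif(k, 5, 30)  # never exceeds the 30 s rule
    }
    dur <- pmin(dur, monitoring[i] * 0.9)
    if (long) dur <- pmax(dur, 30.5)  # AF-positive subjects must qualify
    start <- stats::runif(k, 0, pmax(monitoring[i] - dur, 0))
    data.frame(start_offset = start, duration = dur)
  })
}

#' Generate a synthetic elderly screening cohort
#'
#' Draws one subject per row with the statistical structure of a nationwide
#' AF-screening study of adults aged 65+: truncated-normal ages, independent
#' binary risk factors at specified prevalences (optionally correlated via a
#' Gaussian copula), laboratory values realised so that guideline phenotyping
#' reproduces the intended condition flags, silent AF drawn from a logistic
#' model in the silent-AF effect sizes calibrated to its target prevalence,
#' symptomatic AF drawn among the remaining subjects from the overall-AF
#' effect sizes so that total AF hits its target, ECG episode lists
#' (every AF-positive subject has at least one episode longer than 30 s; a
#' configurable fraction of AF-negative subjects has only sub-30-s episodes),
#' and lognormal effective monitoring times.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` with one row per subject: demographics, history and
#'   medication flags, laboratory values, an `episodes` list-column of
#'   per-episode `start_offset`/`duration` (seconds), `effective_monitoring`
#'   (seconds), `symptomatic`, and the generator truth `latent_af`. The spec
#'   is attached as attribute `"cohort_spec"`. Deterministic given
#'   `spec$seed`.
#' @seealso [phenotype_cohort()] to derive guideline flags and AF status.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_subjects
    age <- rnorm_trunc(n, spec$age_mean, spec$age_sd, lower = spec$age_min)
    X <- draw_covariates(spec, n)
    female <- X[, "male"] == 0
    labs <- draw_labs(X, age, female, spec$lab_distributions)

    eta_saf <- linear_predictor(spec$saf_log_ors, X, age, spec$age_min)
    b0_saf <- calibrate_intercept(eta_saf, spec$target_saf_prevalence)
    saf <- stats::runif(n) < stats::plogis(b0_saf + eta_saf)

    # symptomatic AF among the remaining subjects, calibrated so the overall
    # AF prevalence (silent + symptomatic) meets its target
    eta_af <- linear_predictor(spec$af_log_ors, X, age, spec$age_min)
    p_sym <- (spec$target_af_prevalence - spec$target_saf_prevalence) /
      (1 - spec$target_saf_prevalence)
    b0_sym <- calibrate_intercept(eta_af[!saf], p_sym)
    symptomatic <- rep(FALSE, n)
    symptomatic[!saf] <- stats::runif(sum(!saf)) <
      stats::plogis(b0_sym + eta_af[!saf])
    latent_af <- saf | symptomatic

    med_sec <- spec$monitoring_days_target_median * 86400
    min_sec <- spec$monitoring_days_min * 86400
    u <- stats::runif(n, stats::plnorm(min_sec, log(med_sec), spec$monitoring_logsd), 1)
    monitoring <- stats::qlnorm(u, log(med_sec), spec$monitoring_logsd)

    episodes <- rep(list(data.frame(start_offset = numeric(0),
                                    duration = numeric(0))), n)
    episodes[latent_af] <- draw_episodes(sum(latent_af), monitoring[latent_af],
                                         long = TRUE)
    stress <- !latent_af & stats::runif(n) < spec$sub30_fraction
    episodes[stress] <- draw_episodes(sum(stress), monitoring[stress],
                                      long = FALSE)

    cohort <- data.frame(
      id = sprintf("S%05d", seq_len(n)),
      age = age,
      sex = ifelse(female, "female", "male"),
      mi = X[, "mi"] == 1, chd = X[, "chd"] == 1,
      thyroid = X[, "thyroid"] == 1, pulmonary = X[, "pulmonary"] == 1,
      thromboembolism = X[, "thromboembolism"] == 1, lead = X[, "lead"] == 1,
      ics_tia = X[, "ics_tia"] == 1, pci_cabg = X[, "pci_cabg"] == 1,
      heart_failure = X[, "heart_failure"] == 1,
      physical_activity = X[, "physical_activity"] == 1,
      labs,
      effective_monitoring = monitoring,
      symptomatic = symptomatic,
      latent_af = latent_af
    )
    cohort$episodes <- episodes
    attr(cohort, "cohort_spec") <- spec
    cohort
  })
}
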