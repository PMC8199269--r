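or_estimate <- function(factor, or, se_log, adjusted, n_used,
                        continuity = FALSE, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lo <- exp(log(or) - z * se_log)
  hi <- exp(log(or) + z * se_log)
  p <- 2 * stats::pnorm(-abs(log(or) / se_log))
  data.frame(factor = factor, odds_ratio = or, ci_low = lo, ci_high = hi,
             p_value = p, adjusted = adjusted, n_used = n_used,
             continuity = continuity, stringsAsFactors = FALSE)
}

#' Odds ratio from a 2x2 contingency table
#'
#' Cross-product odds ratio `(a*d)/(b*c)` with the Wald interval on the log
#' scale, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`, and a Wald z p-value. Any zero
#' cell triggers the Haldane-Anscombe continuity correction (0.5 added to all
#' four cells) and sets the `continuity` flag on the estimate.
#'
#' @param exposed_cases,unexposed_cases,exposed_controls,unexposed_controls
#'   Non-negative counts `a`, `b`, `c`, `d`.
#' @param factor Label carried on the returned row.
#' @return A one-row `data.frame`: `factor`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `adjusted` (`FALSE`), `n_used`, `continuity`.
#' @examples
#' contingency_or(413, 267, 1122, 1212)  # OR ~ 1.67
#' @export
contingency_or <- function(exposed_cases, unexposed_cases,
                           exposed_controls, unexposed_controls,
                           factor = "exposure") {
  cells <- c(exposed_cases, unexposed_cases, exposed_controls,
             unexposed_controls)
  if (any(cells < 0)) stopf("all cell counts must be non-negative")
  continuity <- any(cells == 0)
  if (continuity) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or_estimate(factor, (a * d) / (b * c), sqrt(1 / a + 1 / b + 1 / c + 1 / d),
              adjusted = FALSE, n_used = sum(cells), continuity = continuity)
}

#' Group comparisons for a cohort characteristics table
#'
#' Compares AF-negative subjects against either all AF-positive subjects or
#' the silent-AF subgroup: Pearson chi-square without continuity correction
#' for each binary factor, a two-sample t-test (pooled variance by default,
#' Welch optionally) for age. Output is one row per characteristic with group
#' counts/means, percentages and the p-value, in the shape of a study
#' Table 1.
#'
#' @param cohort A phenotyped cohort ([phenotype_cohort()]).
#' @param comparison `"af"` (AF- vs all AF) or `"saf"` (AF- vs silent AF).
#' @param factors Character vector of logical columns to compare; defaults to
#'   the full risk-factor panel.
#' @param welch Use the Welch t-test for age instead of pooled variance.
#' @return `data.frame` with columns `characteristic`, `group0_n`,
#'   `group0_stat`, `group1_n`, `group1_stat`, `statistic`, `p_value`,
#'   `note` (flags expected cells below 1).
#' @export
group_tests <- function(cohort, comparison = c("af", "saf"),
                        factors = c("male", "mi", "chd", "thyroid",
                                    "pulmonary", "thromboembolism", "lead",
                                    "ics_tia", "pci_cabg", "dm",
                                    "heart_failure", "ha", "ckd",
                                    "physical_activity", "obesity",
                                    "hscrp_high", "ntprobnp_high"),
                        welch = FALSE) {
  comparison <- match.arg(comparison)
  g0 <- cohort$af_status == "no_af"
  g1 <- if (comparison == "af") cohort$af_status != "no_af" else
    cohort$af_status == "silent_af"
  if (!any(g0) || !any(g1)) stopf("both comparison groups must be non-empty")

  tt <- stats::t.test(cohort$age[g1], cohort$age[g0], var.equal = !welch)
  rows <- list(data.frame(
    characteristic = "age", group0_n = sum(g0),
    group0_stat = mean(cohort$age[g0]), group1_n = sum(g1),
    group1_stat = mean(cohort$age[g1]),
    statistic = unname(tt$statistic), p_value = tt$p.value, note = "",
    stringsAsFactors = FALSE
  ))
  factors <- intersect(factors, names(cohort))
  for (f in factors) {
    x <- cohort[[f]]
    tab <- rbind(c(sum(x[g0]), sum(!x[g0])), c(sum(x[g1]), sum(!x[g1])))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    note <- if (any(expected < 1)) "expected cell < 1" else ""
    if (any(colSums(tab) == 0)) {  # factor constant in both groups
      stat <- 0; p <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat <- unname(ct$statistic); p <- ct$p.value
    }
    rows[[f]] <- data.frame(
      characteristic = f, group0_n = sum(g0), group0_stat = mean(x[g0]),
      group1_n = sum(g1), group1_stat = mean(x[g1]),
      statistic = stat, p_value = p, note = note, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Multivariable logistic regression odds ratios
#'
#' Maximum-likelihood logistic fit (Newton/IRLS, score tolerance 1e-10, at
#' most 100 iterations) of a binary outcome on a design of predictors, with
#' optional frequency weights (weights rescale the log-likelihood and thus
#' affect point estimates; design-based variance is out of scope and the
#' Wald intervals treat the weights as frequencies). Returns one Wald
#' [contingency_or()]-shaped row per predictor.
#'
#' Fails explicitly on rank-deficient designs (naming the collinear columns)
#' and on separation/non-convergence (naming the worst predictor).
#'
#' @param design `data.frame` or numeric matrix of predictors (no intercept
#'   column; logical columns are coerced to 0/1).
#' @param outcome Logical (or 0/1) vector with both classes present.
#' @param weights Optional positive per-subject weights.
#' @return `data.frame` of per-predictor estimates (`factor`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `adjusted`, `n_used`), with the fitted
#'   intercept as attribute `"intercept"`.
#' @export
fit_logistic <- function(design, outcome, weights = NULL) {
  X <- as.data.frame(design)
  X[] <- lapply(X, function(col) as.numeric(col))
  outcome <- as.logical(outcome)
  if (length(unique(outcome)) < 2) stopf("outcome must contain both classes")
  if (is.null(weights)) weights <- rep(1, length(outcome))
  if (any(weights <= 0)) stopf("weights must be positive")

  M <- cbind(`(Intercept)` = 1, as.matrix(X))
  qrm <- qr(M)
  if (qrm$rank < ncol(M)) {
    aliased <- colnames(M)[qrm$pivot[(qrm$rank + 1):ncol(M)]]
    stopf("design is rank deficient; collinear columns: %s",
          paste(aliased, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm.fit(
    M, as.numeric(outcome), weights = weights,
    family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)
  ))
  coefs <- fit$coefficients
  if (!fit$converged || any(abs(coefs[-1]) > 15)) {
    worst <- names(which.max(abs(coefs[-1])))
    stopf("logistic fit did not converge (possible separation); worst predictor: %s",
          worst)
  }
  # Wald covariance from the weighted information matrix at the MLE
  w <- fit$weights  # mu(1-mu) * frequency weights
  info <- crossprod(M * sqrt(w))
  vc <- chol2inv(chol(info))
  se <- sqrt(diag(vc))
  est <- do.call(rbind, lapply(seq_along(coefs)[-1], function(j) {
    or_estimate(colnames(M)[j], exp(coefs[j]), se[j],
                adjusted = ncol(X) > 1, n_used = length(outcome))
  }))
  attr(est, "intercept") <- unname(coefs[1])
  est
}

#' Poststratification weights toward target population shares
#'
#' Cell weights `target share / sample share` over the interaction of the
#' stratum variables, rescaled to mean 1. Weights adjust point estimates to
#' the target population; no design-based variance is attempted.
#'
#' @param data `data.frame` containing the stratum variables.
#' @param vars Character vector of stratum variable names (e.g. age group,
#'   sex, living environment, region).
#' @param target_shares Named numeric vector of population shares, one per
#'   stratum cell, named by the `.`-separated interaction of `vars` levels
#'   (as produced by `interaction(...)`); must sum to 1.
#' @return Numeric vector of per-subject weights with mean 1.
#' @export
poststratify <- function(data, vars, target_shares) {
  if (abs(sum(target_shares) - 1) > 1e-8) {
    stopf("target shares must sum to 1")
  }
  cells <- as.character(interaction(data[vars], drop = TRUE, sep = "."))
  sample_shares <- table(cells) / length(cells)
  missing <- setdiff(names(sample_shares), names(target_shares))
  if (length(missing)) {
    stopf("no target share for sample cell(s): %s", paste(missing, collapse = ", "))
  }
  w <- as.numeric(target_shares[cells] / sample_shares[cells])
  w / mean(w)
}
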