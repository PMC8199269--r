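# Shared fixtures built in code.

# Published per-draw multivariable odds ratios and p-values for the six score
# factors over the five random splits (p-values printed as "<0.001" are
# encoded as 0.0005; only the p < 0.05 comparison matters).
published_draw_table <- function() {
  factors <- c("male", "ckd", "dm", "age75", "ics_tia", "heart_failure")
  ors <- rbind(
    c(2.39, 1.78, 1.34, 2.66, 1.70, 1.63),
    c(1.54, 1.39, 1.39, 3.30, 1.57, 2.02),
    c(2.13, 1.31, 1.29, 3.10, 1.94, 2.10),
    c(1.99, 1.88, 1.37, 2.34, 1.98, 1.85),
    c(2.50, 1.43, 1.51, 2.83, 1.76, 1.88)
  )
  ps <- rbind(
    c(0.020, 0.002, 0.115, 0.0005, 0.025, 0.016),
    c(0.0005, 0.092, 0.093, 0.0005, 0.073, 0.001),
    c(0.0005, 0.171, 0.197, 0.0005, 0.005, 0.0005),
    c(0.0005, 0.001, 0.086, 0.0005, 0.003, 0.002),
    c(0.0005, 0.066, 0.030, 0.0005, 0.021, 0.002)
  )
  lapply(seq_len(nrow(ors)), function(d) {
    list(draw_index = d,
         estimates = data.frame(factor = factors,
                                odds_ratio = ors[d, ],
                                p_value = ps[d, ],
                                stringsAsFactors = FALSE))
  })
}

# Draws list from arbitrary OR/p matrices (rows = draws, cols = factors).
fake_draws <- function(ors, ps, factors = paste0("f", seq_len(ncol(ors)))) {
  lapply(seq_len(nrow(ors)), function(d) {
    list(draw_index = d,
         estimates = data.frame(factor = factors,
                                odds_ratio = ors[d, ],
                                p_value = ps[d, ],
                                stringsAsFactors = FALSE))
  })
}

# Small generated-and-phenotyped cohort reused across tests.
small_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- phenotype_cohort(generate_cohort(cohort_spec(n_subjects = 2000,
                                                            seed = 42)))
    }
    memo
  }
})

# Independent brute-force AUC oracle: concordance over all case-control
# pairs, ties counted one half.
pair_counting_auc <- function(scores, labels) {
  cases <- scores[as.logical(labels)]
  ctrls <- scores[!as.logical(labels)]
  total <- 0
  for (x in cases) total <- total + sum(x > ctrls) + 0.5 * sum(x == ctrls)
  total / (length(cases) * length(ctrls))
}

# Independent CKD-EPI 2009 evaluation, written directly from the published
# coefficient table rather than via the package's vectorised code path.
ckd_epi_oracle <- function(scr, age, sex) {
  if (sex == "female") {
    k <- 0.7; a <- -0.329; sexfac <- 1.018
  } else {
    k <- 0.9; a <- -0.411; sexfac <- 1
  }
  141 * min(scr / k, 1)^a * max(scr / k, 1)^(-1.209) * 0.993^age * sexfac
}
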