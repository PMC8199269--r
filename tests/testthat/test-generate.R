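test_that("calibrate_intercept matches closed forms and is monotone", {
  eta <- rep(0, 200)
  expect_equal(calibrate_intercept(eta, 0.5), 0, tolerance = 1e-5)
  expect_equal(calibrate_intercept(eta, 0.226), log(0.226 / 0.774),
               tolerance = 1e-4)

  # default silent-AF effect sizes: achieved prevalence within contract
  spec <- cohort_spec(n_subjects = 5000, seed = 3)
  set.seed(3)
  X <- sapply(spec$covariate_prevalences, function(p) rbinom(5000, 1, p))
  age <- 65 + abs(rnorm(5000, 12, 8))
  lo <- spec$saf_log_ors
  eta <- (age - 65) / 5 * lo[["age_per5"]] +
    drop(X[, setdiff(names(lo), "age_per5")] %*% lo[setdiff(names(lo), "age_per5")])
  b0 <- calibrate_intercept(eta, 0.093)
  expect_lt(abs(mean(plogis(b0 + eta)) - 0.093), 0.002)

  # strictly increasing in the target
  targets <- c(0.05, 0.1, 0.3, 0.6, 0.9)
  b0s <- vapply(targets, function(t) calibrate_intercept(eta, t), numeric(1))
  expect_true(all(diff(b0s) > 0))

  expect_error(calibrate_intercept(eta, 0), "in \\(0, 1\\)")
  expect_error(calibrate_intercept(eta, 1), "in \\(0, 1\\)")
  expect_error(calibrate_intercept(c(1, Inf), 0.5), "finite")
})

test_that("generated cohorts are deterministic given the seed", {
  spec <- cohort_spec(n_subjects = 500, seed = 99)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_spec(n_subjects = 500, seed = 100))
  expect_false(identical(c1$age, c3$age))
})

test_that("binary covariates and outcomes recover their target rates", {
  n <- 50000
  cohort <- phenotype_cohort(generate_cohort(cohort_spec(n_subjects = n,
                                                         seed = 5)))
  p <- default_covariate_prevalences()
  # history flags are drawn directly
  for (f in c("mi", "chd", "thyroid", "pulmonary", "thromboembolism",
              "lead", "ics_tia", "pci_cabg", "heart_failure",
              "physical_activity")) {
    expect_lt(abs(mean(cohort[[f]]) - p[[f]]),
              4 * sqrt(p[[f]] * (1 - p[[f]]) / n), label = f)
  }
  # condition flags are realised through labs and recovered by phenotyping
  for (f in c("dm", "ha", "ckd", "obesity", "hscrp_high", "ntprobnp_high")) {
    expect_lt(abs(mean(cohort[[f]]) - p[[f]]),
              4 * sqrt(p[[f]] * (1 - p[[f]]) / n), label = f)
  }
  expect_lt(abs(mean(cohort$male) - 0.509), 0.01)
  # outcome prevalences match the calibration targets
  expect_lt(abs(mean(cohort$saf) - 0.093), 0.01)
  expect_lt(abs(mean(cohort$af_detected) - 0.226), 0.015)
  # detected AF equals the generator truth: the >30 s rule separates groups
  expect_identical(cohort$af_detected, cohort$latent_af)
})

test_that("a null-effect spec reduces to the logit of the target prevalence", {
  lo <- default_log_ors("saf"); lo[] <- 0
  la <- default_log_ors("af"); la[] <- 0
  spec <- cohort_spec(n_subjects = 50000, af_log_ors = la, saf_log_ors = lo,
                      seed = 8)
  cohort <- generate_cohort(spec)
  expect_lt(abs(mean(cohort$latent_af) - 0.226), 0.01)
})

test_that("episode lists respect the 30 s contract", {
  cohort <- small_cohort()
  longest <- vapply(cohort$episodes, function(e) {
    if (nrow(e)) max(e$duration) else 0
  }, numeric(1))
  expect_true(all(longest[cohort$latent_af] > 30))
  expect_true(all(longest[!cohort$latent_af] <= 30))
  # the filter is exercised: some AF-negative subjects have short episodes
  n_short <- sum(!cohort$latent_af & longest > 0)
  expect_gt(n_short, 0)
  expect_lt(abs(n_short / sum(!cohort$latent_af) - 0.15), 0.05)
  # episodes fit inside the monitoring window
  ok <- mapply(function(e, m) {
    !nrow(e) || all(e$start_offset >= 0 & e$start_offset + e$duration <= m)
  }, cohort$episodes, cohort$effective_monitoring)
  expect_true(all(ok))
})

test_that("monitoring times follow the target median and floor", {
  cohort <- small_cohort()
  target <- (23 + (10 * 60 + 26) / 1440) * 86400
  expect_lt(abs(median(cohort$effective_monitoring) / target - 1), 0.05)
  expect_true(all(cohort$effective_monitoring >= 12 * 60))
})

test_that("the Gaussian-copula hook induces the requested association", {
  cc <- matrix(c(1, 0.6, 0.6, 1), 2,
               dimnames = list(c("ckd", "heart_failure"),
                               c("ckd", "heart_failure")))
  spec <- cohort_spec(n_subjects = 20000, covariate_correlation = cc, seed = 7)
  cohort <- phenotype_cohort(generate_cohort(spec))
  expect_gt(cor(cohort$ckd, cohort$heart_failure), 0.2)
  # marginals preserved
  expect_lt(abs(mean(cohort$ckd) - 0.333), 0.02)
  expect_lt(abs(mean(cohort$heart_failure) - 0.223), 0.02)
})

test_that("cohort CSV round-trips through write_cohort/read_cohort", {
  spec <- cohort_spec(n_subjects = 60, seed = 2)
  cohort <- generate_cohort(spec)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".spec.json"))), add = TRUE)
  write_cohort(cohort, path)
  expect_true(file.exists(paste0(path, ".spec.json")))
  back <- read_cohort(path)
  expect_equal(back$age, cohort$age)
  expect_equal(back$symptomatic, cohort$symptomatic)
  expect_equal(back$episodes[[which(cohort$latent_af)[1]]],
               cohort$episodes[[which(cohort$latent_af)[1]]],
               tolerance = 1e-12)
  expect_equal(attr(back, "cohort_spec")$seed, spec$seed)
  # phenotyping the round-tripped cohort gives identical AF status
  expect_identical(phenotype_cohort(back)$af_status,
                   phenotype_cohort(cohort)$af_status)
})
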