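test_that("AUC matches brute-force pair counting and known values", {
  expect_equal(roc_curve(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # 6 case-control pairs: concordant 5, discordant 1
  curve <- roc_curve(c(3, 5, 1, 2, 4), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(curve$auc, 5 / 6, tolerance = 1e-12)
  expect_equal(curve$auc,
               pair_counting_auc(c(3, 5, 1, 2, 4),
                                 c(TRUE, TRUE, FALSE, FALSE, FALSE)),
               tolerance = 1e-12)
  # null labels give chance discrimination
  set.seed(41)
  s <- sample(0:10, 10000, replace = TRUE)
  y <- sample(c(TRUE, FALSE), 10000, replace = TRUE)
  expect_lt(abs(roc_curve(s, y)$auc - 0.5), 0.02)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both cases and controls")
})

test_that("trapezoid AUC equals pair counting across random instances", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    s <- sample(0:6, n, replace = TRUE)        # heavy ties, integer scores
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    curve <- roc_curve(s, y)
    expect_equal(curve$auc, pair_counting_auc(s, y), tolerance = 1e-12)
    # an integer-score ROC has at most (distinct scores + 1) vertices
    expect_lte(nrow(curve$points), length(unique(s)) + 1)
  }
})

test_that("AUC and DeLong interval agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(43)
  for (i in 1:10) {
    n <- 120
    y <- rbinom(n, 1, 0.35)
    if (sum(y) %in% c(0, n)) next
    s <- rnorm(n, mean = y)  # continuous scores
    curve <- roc_curve(s, y)
    ref <- pROC::roc(y, s, direction = "<", quiet = TRUE)
    expect_equal(curve$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
    ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(curve$auc_ci_low, max(0, ci[1]), tolerance = 1e-6)
    expect_equal(curve$auc_ci_high, min(1, ci[3]), tolerance = 1e-6)
    # tied integer scores too
    si <- round(s * 2)
    curve2 <- roc_curve(si, y)
    ref2 <- pROC::roc(y, si, direction = "<", quiet = TRUE)
    expect_equal(curve2$auc, as.numeric(pROC::auc(ref2)), tolerance = 1e-10)
  }
})

test_that("minimal-distance cutoff selection enumerates correctly", {
  # cases {5,6}, controls {1,2,6}: best cutoff 3.5, sens 1, spec 2/3
  curve <- roc_curve(c(5, 6, 1, 2, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  best <- optimal_cutoff(curve)
  expect_equal(best$cutoff, 3.5)
  expect_equal(best$sensitivity, 1)
  expect_equal(best$specificity, 2 / 3, tolerance = 1e-12)
  expect_equal(best$distance, 1 / 3, tolerance = 1e-12)
  # brute-force oracle over all candidate cutoffs
  d <- sqrt((1 - curve$points$sensitivity)^2 + (1 - curve$points$specificity)^2)
  expect_equal(best$distance, min(d), tolerance = 1e-12)

  # perfect separation: distance 0 at the separating midpoint
  perf <- optimal_cutoff(roc_curve(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(perf$distance, 0)
  expect_equal(perf$cutoff, 3.5)

  # tie between two equidistant operating points: lower cutoff wins
  # scores: cases {2,4}, controls {1,3}; cutoffs 1.5 and 3.5 are symmetric
  tie_curve <- roc_curve(c(2, 4, 1, 3), c(TRUE, TRUE, FALSE, FALSE))
  dd <- sqrt((1 - tie_curve$points$sensitivity)^2 +
               (1 - tie_curve$points$specificity)^2)
  stopifnot(sum(abs(dd - min(dd)) < 1e-12) > 1)  # the fixture really ties
  expect_equal(optimal_cutoff(tie_curve)$cutoff, 1.5)
})

test_that("confusion metrics satisfy their identities", {
  set.seed(44)
  s <- sample(0:11, 500, replace = TRUE)
  y <- rbinom(500, 1, plogis((s - 5) / 3))
  m <- cutoff_metrics(s, y, 4.5)
  expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
  expect_equal(m$specificity, m$tn / (m$tn + m$fp))
  expect_equal(m$ppv, m$tp / (m$tp + m$fp))
  expect_equal(m$npv, m$tn / (m$tn + m$fn))
  # Bayes identity: PPV from sensitivity, specificity and prevalence
  pi <- mean(y)
  expect_equal(m$ppv,
               m$sensitivity * pi /
                 (m$sensitivity * pi + (1 - m$specificity) * (1 - pi)),
               tolerance = 1e-12)
  # positives are strictly greater than the cutoff
  expect_equal(m$tp + m$fp, sum(s > 4.5))
})

test_that("evaluate_draws separates derivation and validation correctly", {
  cohort <- small_cohort()
  cfg <- score_config(seed = 51)
  draws <- run_draws(cohort, cfg)
  def <- assign_points(draws, cfg)
  ev <- evaluate_draws(cohort, draws, def)
  usable <- ev$summary[!grepl("mean", ev$summary$cohort), ]
  expect_equal(nrow(usable), 10)  # 5 draws x {derivation, validation}
  expect_setequal(unique(usable$cohort), c("derivation", "validation"))
  # the validation cutoff is the derivation cutoff, never re-optimised
  for (res in ev$draws) {
    expect_equal(res$validation$metrics$cutoff,
                 res$derivation$metrics$cutoff)
  }
  # half-integer cutoffs for an integer score
  expect_true(all(usable$cutoff %% 1 == 0.5))
  # changing validation outcomes cannot move the cutoff (no leakage)
  flipped <- cohort
  vids <- draws[[1]]$validation_ids
  flipped$saf[flipped$id %in% vids] <- !flipped$saf[flipped$id %in% vids]
  flipped$af_status[flipped$id %in% vids & flipped$saf] <- "silent_af"
  ev2 <- evaluate_draws(flipped, draws, def)
  expect_equal(ev2$draws[[1]]$derivation$metrics$cutoff,
               ev$draws[[1]]$derivation$metrics$cutoff)

  # constant scores are flagged degenerate
  flat <- cohort
  flat[, def$factor] <- FALSE
  evf <- evaluate_draws(flat, draws, def)
  expect_true(all(vapply(evf$draws, `[[`, logical(1), "degenerate")))
})
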