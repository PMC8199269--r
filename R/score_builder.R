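#' Configuration for the split-resampling score derivation
#'
#' Parameters of the MR-DASH derivation procedure: the population without
#' overt (symptomatic) AF is randomly split `n_draws` times into derivation
#' (2/3) and validation (1/3) subsets; a multivariable logistic model of
#' silent AF on the six factors is fitted per draw; factors significant in at
#' least `consistency_threshold` draws score the rounded mean odds ratio,
#' the rest score 1 point.
#'
#' @param n_draws Number of random splits (default 5).
#' @param derivation_fraction Derivation share of each split (default 2/3).
#' @param alpha Two-sided Wald significance level (default 0.05).
#' @param consistency_threshold Minimum number of significant draws for
#'   OR-based points (default 4, clamped to `n_draws`).
#' @param factors Ordered score factors; must be logical columns of the
#'   phenotyped cohort. Default: male sex, CKD, diabetes, age >= 75,
#'   stroke/TIA, heart failure.
#' @param or_average `"all"` averages each factor's OR over all draws before
#'   rounding (default); `"significant"` averages only over its significant
#'   draws. Both reproduce the published point values.
#' @param point_overrides Optional named integer vector forcing specific
#'   point values (e.g. `c(heart_failure = 1)` for the published-table
#'   variant of the heart-failure weight).
#' @param seed Integer seed for the splits; draw `d` uses `seed + d`.
#' @return An object of class `score_config`.
#' @export
score_config <- function(n_draws = 5,
                         derivation_fraction = 2 / 3,
                         alpha = 0.05,
                         consistency_threshold = min(4, n_draws),
                         factors = c("male", "ckd", "dm", "age75",
                                     "ics_tia", "heart_failure"),
                         or_average = c("all", "significant"),
                         point_overrides = NULL,
                         seed = 1L) {
  if (derivation_fraction <= 0 || derivation_fraction >= 1) {
    stopf("derivation_fraction must lie strictly between 0 and 1")
  }
  if (consistency_threshold < 1 || consistency_threshold > n_draws) {
    stopf("consistency_threshold must lie in [1, n_draws]")
  }
  structure(
    list(n_draws = as.integer(n_draws),
         derivation_fraction = derivation_fraction,
         alpha = alpha,
         consistency_threshold = as.integer(consistency_threshold),
         factors = factors,
         or_average = match.arg(or_average),
         point_overrides = point_overrides,
         seed = as.integer(seed)),
    class = "score_config"
  )
}

#' Random derivation/validation split of the eligible population
#'
#' Simple random split without replacement: `round(fraction * n)` ids go to
#' the derivation set, the remainder to validation. Reproducible per seed.
#'
#' @param eligible_ids Vector of subject ids (symptomatic-AF subjects must
#'   already be excluded by the caller).
#' @param fraction Derivation fraction.
#' @param seed Integer seed.
#' @param min_n Smallest population the function will split (default 10); a
#'   guard against meaningless derivation sets, relaxable for toy examples.
#' @return List with `derivation_ids` and `validation_ids`.
#' @export
split_population <- function(eligible_ids, fraction = 2 / 3, seed = 1L,
                             min_n = 10) {
  n <- length(eligible_ids)
  if (n < min_n) stopf("refusing to split fewer than %d subjects", min_n)
  n_der <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, n_der))
  list(derivation_ids = eligible_ids[idx],
       validation_ids = eligible_ids[-idx])
}

#' Run the repeated split-and-fit score-derivation draws
#'
#' For each draw, splits the population without overt AF into derivation and
#' validation subsets and fits the multivariable logistic model of silent AF
#' on the score factors over the derivation subset.
#'
#' @param cohort A phenotyped cohort ([phenotype_cohort()]); needs `id`,
#'   `af_status`, `saf` and the factor columns.
#' @param cfg A [score_config()].
#' @return List of class `draw_results`; each element has `draw_index`,
#'   `derivation_ids`, `validation_ids` and `estimates` (the per-factor
#'   odds-ratio table from [fit_logistic()]).
#' @export
run_draws <- function(cohort, cfg = score_config()) {
  missing_f <- setdiff(cfg$factors, names(cohort))
  if (length(missing_f)) {
    stopf("cohort lacks score factor column(s): %s",
          paste(missing_f, collapse = ", "))
  }
  eligible <- cohort[cohort$af_status != "symptomatic_af", , drop = FALSE]
  draws <- lapply(seq_len(cfg$n_draws), function(d) {
    split <- split_population(eligible$id, cfg$derivation_fraction,
                              seed = cfg$seed + d)
    der <- eligible[eligible$id %in% split$derivation_ids, , drop = FALSE]
    est <- tryCatch(
      fit_logistic(der[cfg$factors], der$saf),
      error = function(e) stopf("draw %d: %s", d, conditionMessage(e))
    )
    list(draw_index = d,
         derivation_ids = split$derivation_ids,
         validation_ids = split$validation_ids,
         estimates = est)
  })
  structure(draws, class = "draw_results")
}

#' Assign integer score points from the draw evidence
#'
#' Counts, per factor, the draws with Wald p below `alpha`. Factors
#' significant in at least `consistency_threshold` draws receive
#' `round(mean OR)` points (half away from zero, floored at 1); the
#' remaining factors receive 1 point.
#'
#' @param draws A `draw_results` list from [run_draws()], or any list whose
#'   elements carry an `estimates` odds-ratio table.
#' @param cfg A [score_config()].
#' @return An object of class `score_definition`: a `data.frame` with
#'   `factor`, `points`, `n_significant`, `mean_or`, and attribute
#'   `max_score`.
#' @export
assign_points <- function(draws, cfg = score_config()) {
  if (!length(draws)) stopf("at least one draw is required")
  est <- lapply(draws, `[[`, "estimates")
  factors <- est[[1]]$factor
  ors <- sapply(est, function(e) e$odds_ratio[match(factors, e$factor)])
  ps <- sapply(est, function(e) e$p_value[match(factors, e$factor)])
  ors <- matrix(ors, nrow = length(factors))
  ps <- matrix(ps, nrow = length(factors))
  n_sig <- rowSums(ps < cfg$alpha)
  mean_or <- vapply(seq_along(factors), function(i) {
    if (cfg$or_average == "significant" && n_sig[i] > 0) {
      mean(ors[i, ps[i, ] < cfg$alpha])
    } else {
      mean(ors[i, ])
    }
  }, numeric(1))
  points <- ifelse(n_sig >= cfg$consistency_threshold,
                   pmax(1L, as.integer(round_half_up(mean_or))), 1L)
  if (!is.null(cfg$point_overrides)) {
    ov <- cfg$point_overrides
    points[match(names(ov), factors)] <- as.integer(ov)
  }
  def <- data.frame(factor = factors, points = points,
                    n_significant = n_sig, mean_or = mean_or,
                    stringsAsFactors = FALSE)
  structure(def, max_score = sum(points), class = c("score_definition",
                                                    "data.frame"))
}

#' @export
print.score_definition <- function(x, ...) {
  cat("Integer risk score definition (max", attr(x, "max_score"), "points)\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Apply a score definition to subjects
#'
#' Sums each subject's points over the factors they carry. Subjects with a
#' missing factor flag are excluded and logged in the `"exclusions"`
#' attribute.
#'
#' @param cohort Phenotyped cohort containing the factor columns.
#' @param score A [assign_points()] `score_definition`.
#' @return Integer vector of scores in `[0, max_score]`, named by subject id
#'   when available, with excluded ids in the `"exclusions"` attribute.
#' @export
score_subjects <- function(cohort, score) {
  missing_f <- setdiff(score$factor, names(cohort))
  if (length(missing_f)) {
    stopf("cohort lacks score factor column(s): %s",
          paste(missing_f, collapse = ", "))
  }
  flags <- as.matrix(as.data.frame(lapply(cohort[score$factor], as.numeric)))
  complete <- stats::complete.cases(flags)
  scores <- as.integer(flags[complete, , drop = FALSE] %*% score$points)
  if (!is.null(cohort$id)) names(scores) <- cohort$id[complete]
  attr(scores, "exclusions") <- if (all(complete)) character(0) else {
    as.character(cohort$id[!complete] %||% which(!complete))
  }
  scores
}
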