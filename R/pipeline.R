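#' Headline prevalence arithmetic for a screening cohort
#'
#' Computes the percentages a screening study reports up front: overall AF,
#' symptomatic AF and silent AF prevalence (of the whole cohort), monitoring
#' coverage, and the silent share among AF-positive subjects. Percentages are
#' rounded to one decimal place.
#'
#' @param n_total Cohort size.
#' @param n_af AF-positive subjects (symptomatic or silent).
#' @param n_symptomatic Symptomatic-AF subjects.
#' @param n_saf Silent-AF subjects.
#' @param n_monitored Subjects with usable ECG monitoring.
#' @return `data.frame` with `quantity`, `numerator`, `denominator`,
#'   `percent`.
#' @examples
#' prevalence_report(3014, 680, 401, 279, 2974)
#' @export
prevalence_report <- function(n_total, n_af, n_symptomatic, n_saf,
                              n_monitored = n_total) {
  if (n_symptomatic + n_saf != n_af) {
    stopf("symptomatic (%d) + silent (%d) must equal AF-positive (%d)",
          n_symptomatic, n_saf, n_af)
  }
  rows <- data.frame(
    quantity = c("af_prevalence", "symptomatic_af_prevalence",
                 "saf_prevalence", "monitoring_coverage", "saf_share_of_af"),
    numerator = c(n_af, n_symptomatic, n_saf, n_monitored, n_saf),
    denominator = c(n_total, n_total, n_total, n_total, n_af),
    stringsAsFactors = FALSE
  )
  rows$percent <- round(100 * rows$numerator / rows$denominator, 1)
  rows
}

#' Pipeline configuration
#'
#' Bundles every stage's options for [run_pipeline()].
#'
#' @param cohort A [cohort_spec()] to simulate from, or a path to a cohort
#'   CSV written by [write_cohort()].
#' @param thresholds A [phenotype_thresholds()].
#' @param score A [score_config()].
#' @param outcome Outcome for the association table: `"saf"` or `"af"`; both
#'   are always reported, this selects the primary.
#' @param weights Optional list `list(vars =, target_shares =)` passed to
#'   [poststratify()]; default `NULL` (unweighted).
#' @param re_derive_validation Passed to [evaluate_draws()].
#' @param output_dir Directory for the report bundle; created if missing.
#' @param seed Global seed; overrides the seeds inside `cohort` and `score`
#'   when not `NULL`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            thresholds = phenotype_thresholds(),
                            score = score_config(),
                            outcome = c("saf", "af"),
                            weights = NULL,
                            re_derive_validation = FALSE,
                            output_dir = NULL,
                            seed = NULL) {
  if (is.character(cohort) && !file.exists(cohort)) {
    stopf("cohort file not found: %s", cohort)
  }
  structure(
    list(cohort = cohort, thresholds = thresholds, score = score,
         outcome = match.arg(outcome), weights = weights,
         re_derive_validation = re_derive_validation,
         output_dir = output_dir, seed = seed),
    class = "pipeline_config"
  )
}

write_report <- function(obj, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  jsonlite::write_json(obj, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  if (is.data.frame(obj)) {
    utils::write.csv(obj, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> phenotype -> characteristics and odds-ratio tables
#' -> score derivation draws -> point assignment -> ROC evaluation. When
#' `cfg$output_dir` is set, each report is written as JSON (and CSV for
#' tables) together with a run manifest (config, seeds, package version,
#' config hash); results are a pure function of the configuration.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `pipeline_result`: `cohort` (phenotyped),
#'   `prevalence`, `characteristics` (group tests for both comparisons),
#'   `associations` (multivariable OR tables for AF and SAF), `draws`,
#'   `score`, `evaluation`, `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  score_cfg <- cfg$score
  if (is.character(cfg$cohort)) {
    cohort <- read_cohort(cfg$cohort)
  } else {
    spec <- cfg$cohort
    if (!is.null(cfg$seed)) spec$seed <- as.integer(cfg$seed)
    cohort <- generate_cohort(spec)
  }
  if (!is.null(cfg$seed)) score_cfg$seed <- as.integer(cfg$seed)

  cohort <- phenotype_cohort(cohort, cfg$thresholds)
  status <- table(cohort$af_status)
  prevalence <- prevalence_report(
    n_total = nrow(cohort),
    n_af = sum(status[c("symptomatic_af", "silent_af")]),
    n_symptomatic = status[["symptomatic_af"]],
    n_saf = status[["silent_af"]],
    n_monitored = sum(cohort$effective_monitoring > 0)
  )

  characteristics <- list(af = group_tests(cohort, "af"),
                          saf = group_tests(cohort, "saf"))

  w <- if (!is.null(cfg$weights)) {
    poststratify(cohort, cfg$weights$vars, cfg$weights$target_shares)
  } else NULL
  assoc_factors <- c("age_per5", "male", "mi", "chd", "thyroid", "pulmonary",
                     "thromboembolism", "lead", "ics_tia", "pci_cabg", "dm",
                     "heart_failure", "ha", "ckd", "physical_activity",
                     "obesity", "hscrp_high", "ntprobnp_high")
  design <- cohort[setdiff(assoc_factors, "age_per5")]
  design <- cbind(age_per5 = (cohort$age - 65) / 5, design)
  associations <- list(
    af = fit_logistic(design, cohort$af_status != "no_af", weights = w),
    saf = fit_logistic(design[cohort$af_status != "symptomatic_af", ],
                       cohort$saf[cohort$af_status != "symptomatic_af"],
                       weights = w[cohort$af_status != "symptomatic_af"])
  )

  draws <- run_draws(cohort, score_cfg)
  score <- assign_points(draws, score_cfg)
  evaluation <- evaluate_draws(cohort, draws, score,
                               re_derive_validation = cfg$re_derive_validation)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mrdash")),
    r_version = R.version.string,
    seed = cfg$seed %||% (if (is.character(cfg$cohort)) score_cfg$seed
                          else cfg$cohort$seed),
    n_subjects = nrow(cohort),
    n_excluded = nrow(attr(cohort, "exclusions") %||% data.frame()),
    config = serialize_config(cfg)
  )
  manifest$config_hash <- hash_config(manifest$config)

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(prevalence, cfg$output_dir, "prevalence")
    write_report(characteristics$af, cfg$output_dir, "table1_af")
    write_report(characteristics$saf, cfg$output_dir, "table1_saf")
    write_report(associations$af, cfg$output_dir, "table2_af")
    write_report(associations$saf, cfg$output_dir, "table2_saf")
    table3 <- do.call(rbind, lapply(draws, function(d) {
      cbind(draw = d$draw_index, d$estimates)
    }))
    write_report(table3, cfg$output_dir, "table3_draws")
    write_report(as.data.frame(score), cfg$output_dir, "score_definition")
    write_report(evaluation$summary, cfg$output_dir, "table4_metrics")
    roc_points <- do.call(rbind, lapply(evaluation$draws, function(res) {
      if (res$degenerate) return(NULL)
      rbind(cbind(draw = res$draw_index, cohort = "derivation",
                  res$derivation$roc$points),
            cbind(draw = res$draw_index, cohort = "validation",
                  res$validation$roc$points))
    }))
    write_report(roc_points, cfg$output_dir, "roc_points")
    write_report(manifest, cfg$output_dir, "manifest")
  }

  structure(
    list(cohort = cohort, prevalence = prevalence,
         characteristics = characteristics, associations = associations,
         draws = draws, score = score, evaluation = evaluation,
         manifest = manifest),
    class = "pipeline_result"
  )
}

serialize_config <- function(cfg) {
  clean <- lapply(unclass(cfg), function(x) {
    if (inherits(x, c("cohort_spec", "phenotype_thresholds", "score_config"))) {
      unclass(x)
    } else x
  })
  clean
}

hash_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA, null = "null")), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Screening-cohort analysis pipeline result\n")
  cat(sprintf("  %d subjects; AF %.1f%%, silent AF %.1f%%\n",
              x$manifest$n_subjects,
              x$prevalence$percent[x$prevalence$quantity == "af_prevalence"],
              x$prevalence$percent[x$prevalence$quantity == "saf_prevalence"]))
  cat(sprintf("  score: max %d points; mean derivation AUC %.3f, validation %.3f\n",
              attr(x$score, "max_score"),
              x$evaluation$summary$auc[x$evaluation$summary$cohort == "derivation_mean"],
              x$evaluation$summary$auc[x$evaluation$summary$cohort == "validation_mean"]))
  invisible(x)
}
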