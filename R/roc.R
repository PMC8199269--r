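#' ROC curve, AUC and DeLong confidence interval
#'
#' Builds the ROC curve of a score against a binary label over candidate
#' cutoffs placed at the midpoints between consecutive distinct observed
#' scores plus sentinels below the minimum and above the maximum (for
#' integer scores these are the half-integer thresholds). "Positive" means
#' score strictly greater than the cutoff. The AUC is computed by the
#' trapezoid rule, which for a step ROC equals the pair-counting concordance
#' statistic with ties counted 1/2; its 95% CI uses the DeLong placement
#' variance.
#'
#' @param scores Numeric scores, higher = more likely a case.
#' @param labels Logical (or 0/1) case indicator; both classes required.
#' @param conf Confidence level for the AUC interval (default 0.95).
#' @return Object of class `roc_curve`: list with `points` (a `data.frame`
#'   of `cutoff`, `sensitivity`, `specificity`, `fpr`, `tp`, `fp`, `tn`,
#'   `fn`, ordered by decreasing cutoff), `auc`, `auc_ci_low`, `auc_ci_high`,
#'   `n_cases`, `n_controls`.
#' @examples
#' roc_curve(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc  # 1
#' @export
roc_curve <- function(scores, labels, conf = 0.95) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stopf("scores and labels must be complete")
  if (!any(labels) || all(labels)) {
    stopf("ROC analysis requires both cases and controls")
  }
  s <- sort(unique(scores))
  cutoffs <- if (length(s) == 1) {
    c(s - 0.5, s + 0.5)
  } else {
    c(s[1] - 0.5, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 0.5)
  }
  cutoffs <- sort(cutoffs, decreasing = TRUE)
  n_case <- sum(labels); n_ctrl <- sum(!labels)
  pts <- do.call(rbind, lapply(cutoffs, function(cut) {
    pos <- scores > cut
    tp <- sum(pos & labels); fp <- sum(pos & !labels)
    data.frame(cutoff = cut, sensitivity = tp / n_case,
               specificity = (n_ctrl - fp) / n_ctrl,
               fpr = fp / n_ctrl, tp = tp, fp = fp,
               tn = n_ctrl - fp, fn = n_case - tp)
  }))
  auc <- sum(diff(pts$fpr) * (pts$sensitivity[-1] + pts$sensitivity[-nrow(pts)]) / 2)

  # DeLong placements: per-case and per-control concordance components
  case_scores <- scores[labels]; ctrl_scores <- scores[!labels]
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(case_scores, function(x) mean(psi(x, ctrl_scores)), numeric(1))
  v01 <- vapply(ctrl_scores, function(y) mean(psi(case_scores, y)), numeric(1))
  var_auc <- stats::var(v10) / n_case + stats::var(v01) / n_ctrl
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(max(var_auc, 0))
  structure(
    list(points = pts, auc = auc,
         auc_ci_low = max(0, auc - half), auc_ci_high = min(1, auc + half),
         n_cases = n_case, n_controls = n_ctrl),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC %.3f (95%% CI %.3f-%.3f), %d cases / %d controls, %d cutoffs\n",
              x$auc, x$auc_ci_low, x$auc_ci_high, x$n_cases, x$n_controls,
              nrow(x$points)))
  invisible(x)
}

cutoff_row_metrics <- function(row) {
  data.frame(
    cutoff = row$cutoff,
    sensitivity = row$sensitivity, specificity = row$specificity,
    ppv = if (row$tp + row$fp > 0) row$tp / (row$tp + row$fp) else NA_real_,
    npv = if (row$tn + row$fn > 0) row$tn / (row$tn + row$fn) else NA_real_,
    tp = row$tp, fp = row$fp, tn = row$tn, fn = row$fn
  )
}

#' Operating point by minimal distance to the ideal corner (0, 1)
#'
#' Selects the cutoff minimising the Euclidean distance
#' `sqrt((1 - sensitivity)^2 + (1 - specificity)^2)` in ROC space; ties are
#' broken toward the lower cutoff. Metrics are computed with "positive"
#' meaning score strictly greater than the cutoff.
#'
#' @param curve A [roc_curve()].
#' @return One-row `data.frame`: `cutoff`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `tp`, `fp`, `tn`, `fn`, plus a `distance` column.
#' @export
optimal_cutoff <- function(curve) {
  pts <- curve$points
  if (nrow(pts) < 2) stopf("degenerate ROC curve")
  d <- sqrt((1 - pts$sensitivity)^2 + (1 - pts$specificity)^2)
  best <- which(abs(d - min(d)) < 1e-12)
  pick <- best[which.min(pts$cutoff[best])]
  out <- cutoff_row_metrics(pts[pick, ])
  out$distance <- d[pick]
  out
}

#' Confusion-matrix metrics at a fixed cutoff
#'
#' Applies a pre-selected cutoff (e.g. one chosen on a derivation cohort) to
#' new scores without re-optimising, so validation labels never influence the
#' operating point.
#'
#' @param scores,labels As in [roc_curve()].
#' @param cutoff Score threshold; positives are `scores > cutoff`.
#' @return One-row `data.frame` as in [optimal_cutoff()] (without
#'   `distance`).
#' @export
cutoff_metrics <- function(scores, labels, cutoff) {
  labels <- as.logical(labels)
  pos <- scores > cutoff
  row <- data.frame(cutoff = cutoff,
                    tp = sum(pos & labels), fp = sum(pos & !labels),
                    tn = sum(!pos & !labels), fn = sum(!pos & labels))
  row$sensitivity <- row$tp / (row$tp + row$fn)
  row$specificity <- row$tn / (row$tn + row$fp)
  cutoff_row_metrics(row)
}

#' Evaluate a score over the derivation/validation draws
#'
#' For each draw: scores all eligible subjects, computes the ROC curve and
#' AUC on the derivation and validation subsets, selects the
#' minimal-distance cutoff on the derivation subset only, and applies it
#' unchanged to the validation subset. Draws whose validation or derivation
#' subset contains a single outcome class are flagged degenerate and
#' excluded from the summary means.
#'
#' @param cohort Phenotyped cohort.
#' @param draws [run_draws()] output.
#' @param score [assign_points()] output.
#' @param re_derive_validation Also report a cutoff re-derived on the
#'   validation subset (default `FALSE`; the derivation cutoff remains the
#'   primary result either way).
#' @return Object of class `score_evaluation`: list with `draws` (per draw:
#'   `derivation`/`validation` ROC curves and metrics) and `summary`
#'   (per-draw metric table with a trailing mean row).
#' @export
evaluate_draws <- function(cohort, draws, score, re_derive_validation = FALSE) {
  scores <- score_subjects(cohort, score)
  outcome <- cohort$saf
  names(outcome) <- cohort$id
  per_draw <- lapply(draws, function(dr) {
    res <- list(draw_index = dr$draw_index, degenerate = FALSE)
    for (part in c("derivation", "validation")) {
      ids <- dr[[paste0(part, "_ids")]]
      ids <- ids[ids %in% names(scores)]
      s <- scores[ids]; y <- outcome[ids]
      if (!any(y) || all(y) || length(unique(s)) < 2) {
        res$degenerate <- TRUE
        next
      }
      res[[part]] <- list(roc = roc_curve(s, y))
    }
    if (res$degenerate) return(res)
    res$derivation$metrics <- optimal_cutoff(res$derivation$roc)
    cut <- res$derivation$metrics$cutoff
    ids_v <- dr$validation_ids[dr$validation_ids %in% names(scores)]
    res$validation$metrics <- cutoff_metrics(scores[ids_v], outcome[ids_v], cut)
    if (re_derive_validation) {
      res$validation$rederived <- optimal_cutoff(res$validation$roc)
    }
    res
  })
  rows <- list()
  for (res in per_draw) {
    if (res$degenerate) next
    for (part in c("derivation", "validation")) {
      m <- res[[part]]$metrics
      rows[[length(rows) + 1]] <- data.frame(
        draw = res$draw_index, cohort = part,
        auc = res[[part]]$roc$auc,
        auc_ci_low = res[[part]]$roc$auc_ci_low,
        auc_ci_high = res[[part]]$roc$auc_ci_high,
        cutoff = m$cutoff, sensitivity = m$sensitivity,
        specificity = m$specificity, ppv = m$ppv, npv = m$npv,
        stringsAsFactors = FALSE
      )
    }
  }
  summary <- do.call(rbind, rows)
  if (!is.null(summary)) {
    for (part in c("derivation", "validation")) {
      sub <- summary[summary$cohort == part, ]
      mean_row <- data.frame(
        draw = NA_integer_, cohort = paste0(part, "_mean"),
        auc = mean(sub$auc), auc_ci_low = NA_real_, auc_ci_high = NA_real_,
        cutoff = NA_real_, sensitivity = mean(sub$sensitivity),
        specificity = mean(sub$specificity), ppv = mean(sub$ppv),
        npv = mean(sub$npv), stringsAsFactors = FALSE
      )
      summary <- rbind(summary, mean_row)
    }
  }
  structure(list(draws = per_draw, summary = summary),
            class = "score_evaluation")
}

#' @export
print.score_evaluation <- function(x, ...) {
  cat("Score evaluation over", sum(!vapply(x$draws, `[[`, logical(1),
                                           "degenerate")), "usable draws\n")
  print.data.frame(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
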