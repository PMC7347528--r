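#' Pipeline configuration
#'
#' Exactly one data source must be supplied: either paths to a cohort CSV
#' and a definition file, or a simulation scenario (a YAML path or a list
#' with `definition` and `config` as returned by [read_scenario()]).
#'
#' @param cohort_path CSV cohort path (with `definition_path`).
#' @param definition_path YAML/JSON scorecard definition path.
#' @param scenario scenario YAML path or scenario list.
#' @param output_dir optional directory for [write_report()] artifacts.
#' @param cutoff high-risk threshold (default: the definition's).
#' @param p_enter,p_remove updating thresholds (default 0.20).
#' @param m imputations (default 20).
#' @param n_iterations chained-equation sweeps (default 10).
#' @param ci_method AUC CI method (default `"delong"`).
#' @param rounding point rounding mode (default `"nearest"`).
#' @param reference rescaling denominator, `"full_model"` or
#'   `"reference_model"` (see [run_update()]).
#' @param development_fraction split fraction when the cohort arrives
#'   unassigned (default 2/3).
#' @param seed master seed for simulation and imputation.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_path = NULL, definition_path = NULL,
                            scenario = NULL, output_dir = NULL,
                            cutoff = NULL, p_enter = 0.20, p_remove = 0.20,
                            m = 20L, n_iterations = 10L,
                            ci_method = "delong", rounding = "nearest",
                            reference = "full_model",
                            development_fraction = 2 / 3, seed = 1L) {
  if (is.null(scenario) == is.null(cohort_path)) {
    stop("supply exactly one of {cohort_path, scenario}")
  }
  if (!is.null(cohort_path) && is.null(definition_path)) {
    stop("cohort_path requires definition_path")
  }
  structure(list(cohort_path = cohort_path, definition_path = definition_path,
                 scenario = scenario, output_dir = output_dir, cutoff = cutoff,
                 p_enter = p_enter, p_remove = p_remove, m = as.integer(m),
                 n_iterations = as.integer(n_iterations),
                 ci_method = ci_method, rounding = rounding,
                 reference = reference,
                 development_fraction = development_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end scorecard evaluation pipeline
#'
#' Replicates the study design: (1) a temporal development/validation split
#' is assigned if absent; (2) the original cumulative score is validated on
#' the complete cases of the validation split (domain validation), with
#' predicted probabilities from a score model fitted on development
#' complete cases; (3) the development split is multiply imputed (low-
#' incidence items excluded from the chained-equations model); (4) the
#' four-step updating procedure runs on the imputed development data;
#' (5) the updated score is validated on exactly the same validation
#' participants, the fixed denominator making the sensitivity comparison
#' fair. The validation split never enters imputation or updating (checked
#' by participant-id disjointness).
#'
#' @param config a [pipeline_config()].
#' @return object of class `study_report`: list with `original_validation`
#'   and `updated_validation` (both `validation_report`s on the identical
#'   participant set), `development_or_high`, `update_model`,
#'   `updated_scorecard`, `median_score`, `score_iqr`, `outcome_rate`,
#'   `n_development`, `n_validation`, and a `provenance` echo of the
#'   configuration.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  if (!is.null(config$scenario)) {
    sc <- if (is.character(config$scenario)) {
      read_scenario(config$scenario, seed = config$seed)
    } else config$scenario
    definition <- sc$definition
    cfg <- sc$config
    x <- generate_cohort(definition, cfg)
    x <- inject_missingness(x, cfg, definition)
    dev_frac <- cfg$development_fraction
  } else {
    definition <- read_definition(config$definition_path)
    x <- read_cohort(config$cohort_path, definition)
    dev_frac <- config$development_fraction
  }
  if (all(x$split == "unassigned")) {
    x <- assign_temporal_split(x, dev_frac)
  }
  cutoff <- config$cutoff %||% definition_cutoff(definition)

  dev <- cohort_split(x, "development")
  val <- cohort_split(x, "validation")
  if (length(intersect(dev$participant_id, val$participant_id)) > 0L) {
    stop("leakage guard: development and validation sets share participants")
  }
  check_two_classes(dev$outcome)
  check_two_classes(val$outcome)

  scores_all <- compute_cumulative_score(x, definition)
  dev_scores <- compute_cumulative_score(dev, definition)
  or_dev <- odds_ratio(classify_high_risk(dev_scores, cutoff), dev$outcome)

  # domain validation of the original score on validation complete cases
  dev_cc <- dev[is_complete_case(dev, definition), , drop = FALSE]
  val_cc <- val[is_complete_case(val, definition), , drop = FALSE]
  # complete cases are first-trimester complete; any unanswered
  # second-trimester item scores 0, as on a partially filled card
  dev_cc_scores <- compute_cumulative_score(dev_cc, definition, "zero")
  val_cc_scores <- compute_cumulative_score(val_cc, definition, "zero")
  score_model <- fit_score_logit(dev_cc_scores, dev_cc$outcome)
  pred_orig <- stats::plogis(score_model$intercept +
                               score_model$beta_per_point * val_cc_scores)
  original_validation <- build_validation_report(
    val_cc_scores, val_cc$outcome, cutoff = cutoff,
    predicted_probs = pred_orig, ci_method = config$ci_method
  )

  # imputation and updating on the development split only
  stack <- mice_impute(dev, definition, m = config$m,
                       n_iterations = config$n_iterations, seed = config$seed)
  upd <- run_update(stack, definition, p_enter = config$p_enter,
                    p_remove = config$p_remove, rounding = config$rounding,
                    reference = config$reference %||% "full_model")

  # re-validation of the updated score on the identical participant set
  upd_val_scores <- compute_updated_score(val_cc, upd$scorecard, "zero")
  upd_dev_scores <- compute_updated_score(dev_cc, upd$scorecard, "zero")
  upd_model <- fit_score_logit(upd_dev_scores, dev_cc$outcome)
  pred_upd <- stats::plogis(upd_model$intercept +
                              upd_model$beta_per_point * upd_val_scores)
  updated_validation <- build_validation_report(
    upd_val_scores, val_cc$outcome, cutoff = cutoff,
    predicted_probs = pred_upd, ci_method = config$ci_method
  )

  report <- structure(list(
    original_validation = original_validation,
    updated_validation = updated_validation,
    development_or_high = or_dev,
    overall_or_high = odds_ratio(classify_high_risk(scores_all, cutoff), x$outcome),
    update_model = upd$model,
    updated_scorecard = upd$scorecard,
    development_score_model = score_model[c("intercept", "beta_per_point",
                                            "se_beta", "model_chi2")],
    median_score = stats::median(scores_all),
    score_iqr = unname(stats::quantile(scores_all, c(0.25, 0.75))),
    outcome_rate = mean(x$outcome),
    n = nrow(x), n_development = nrow(dev), n_validation = nrow(val),
    n_validation_complete = nrow(val_cc),
    participant_missing_rate = participant_missing_rate(x, definition),
    provenance = list(
      cutoff = cutoff, p_enter = config$p_enter, p_remove = config$p_remove,
      m = config$m, n_iterations = config$n_iterations,
      ci_method = config$ci_method, rounding = config$rounding,
      seed = config$seed,
      scenario = if (is.character(config$scenario)) config$scenario else
        if (!is.null(config$scenario)) "inline scenario" else config$cohort_path,
      package_version = as.character(utils::packageVersion("scoreupdate"))
    )
  ), class = "study_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> n = %d (development %d / validation %d), outcome rate %.1f%%\n",
              x$n, x$n_development, x$n_validation, 100 * x$outcome_rate))
  cat(sprintf("  median score %d (IQR %d-%d)\n", x$median_score,
              x$score_iqr[1], x$score_iqr[2]))
  cat("  original score, validation set:\n    ")
  cat(sprintf("AUC %.3f (%.3f-%.3f), sens %.1f%%, spec %.1f%%\n",
              x$original_validation$auc, x$original_validation$auc_ci[1],
              x$original_validation$auc_ci[2],
              100 * x$original_validation$sensitivity,
              100 * x$original_validation$specificity))
  cat("  updated score, validation set:\n    ")
  cat(sprintf("AUC %.3f (%.3f-%.3f), sens %.1f%%, spec %.1f%%\n",
              x$updated_validation$auc, x$updated_validation$auc_ci[1],
              x$updated_validation$auc_ci[2],
              100 * x$updated_validation$sensitivity,
              100 * x$updated_validation$specificity))
  cat(sprintf("  shrinkage %.3f; %d item(s) updated\n",
              x$update_model$shrinkage,
              sum(x$update_model$additional_points > 0L)))
  invisible(x)
}

report_to_list <- function(x) {
  vr <- function(r) list(
    auc = r$auc, auc_ci = r$auc_ci, ci_method = r$ci_method,
    calib_intercept = r$calib_intercept, calib_slope = r$calib_slope,
    sensitivity = r$sensitivity, specificity = r$specificity,
    or_high = r$or_high, or_ci = r$or_ci, n = r$n, n_events = r$n_events,
    cutoff = r$cutoff
  )
  um <- x$update_model
  list(
    original_validation = vr(x$original_validation),
    updated_validation = vr(x$updated_validation),
    development_or_high = x$development_or_high[c("or", "ci")],
    overall_or_high = x$overall_or_high[c("or", "ci")],
    update_model = list(
      candidates = um$candidates, selected_items = um$selected_items,
      raw_betas = as.list(um$raw_betas), beta_score = um$beta_score,
      model_chi2 = um$model_chi2, df_considered = um$df_considered,
      shrinkage = um$shrinkage,
      dropped_counterintuitive = um$dropped_counterintuitive,
      review_required = um$review_required,
      additional_points = as.list(um$additional_points),
      beta_per_point_reference = um$beta_per_point_reference,
      reference_beta_per_point = um$reference_beta_per_point,
      settings = um$settings
    ),
    development_score_model = x$development_score_model,
    median_score = x$median_score, score_iqr = x$score_iqr,
    outcome_rate = x$outcome_rate, n = x$n,
    n_development = x$n_development, n_validation = x$n_validation,
    n_validation_complete = x$n_validation_complete,
    participant_missing_rate = x$participant_missing_rate,
    provenance = x$provenance
  )
}

#' Write pipeline artifacts
#'
#' Emits `study_report.json`, the candidate-screening table and calibration
#' curves as CSV, the updated scorecard as YAML, and (when ggplot2 is
#' available) a calibration plot.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @param plot write `calibration.pdf` (default: only if ggplot2 installed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir,
                         plot = requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "study_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(as.data.frame(report$update_model$screen),
                   file.path(dir, "screening.csv"), row.names = FALSE)
  for (side in c("original", "updated")) {
    r <- report[[paste0(side, "_validation")]]
    if (!is.null(r$calib_curve)) {
      utils::write.csv(r$calib_curve,
                       file.path(dir, paste0("calibration_", side, ".csv")),
                       row.names = FALSE)
    }
  }
  write_definition(report$updated_scorecard,
                   file.path(dir, "updated_scorecard.yaml"))
  if (isTRUE(plot) && !is.null(report$original_validation$calib_curve)) {
    p <- plot_calibration(report$original_validation)
    suppressMessages(ggplot2::ggsave(file.path(dir, "calibration.pdf"), p,
                                     width = 5, height = 5))
  }
  invisible(dir)
}
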