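#' Logistic regression of outcome on the cumulative score
#'
#' The reference ("univariate") model of the updating procedure: a
#' maximum-likelihood logistic fit of the binary outcome on the integer
#' cumulative score. The slope is the log-odds change per one-point score
#' increase.
#'
#' @param scores integer score vector.
#' @param outcome binary 0/1 vector.
#' @return list with `intercept`, `beta_per_point`, their standard errors
#'   (`se_intercept`, `se_beta`), `model_chi2` (likelihood-ratio statistic
#'   vs the intercept-only model) and the underlying `glm` fit.
#' @export
fit_score_logit <- function(scores, outcome) {
  check_two_classes(outcome)
  if (length(scores) != length(outcome)) stop("length mismatch")
  fit <- suppressWarnings(stats::glm(outcome ~ scores, family = stats::binomial()))
  if (!fit$converged) stop("non-convergence in score logistic model")
  p <- fit$fitted.values
  if (any(p < 1e-10) || any(p > 1 - 1e-10)) {
    stop("perfect separation in score logistic model")
  }
  se <- sqrt(diag(stats::vcov(fit)))
  list(intercept = unname(stats::coef(fit)[1]),
       beta_per_point = unname(stats::coef(fit)[2]),
       se_intercept = unname(se[1]), se_beta = unname(se[2]),
       model_chi2 = unname(fit$null.deviance - fit$deviance),
       fit = fit)
}

check_two_classes <- function(outcome) {
  if (length(outcome) == 0L) stop("empty input")
  if (length(unique(outcome[!is.na(outcome)])) < 2L) {
    stop("both outcome classes must be present")
  }
  invisible(TRUE)
}

#' Area under the ROC curve with a confidence interval
#'
#' The AUC is the normalized Mann--Whitney statistic,
#' `P(score_case > score_control) + 0.5 P(tie)`, computed from midranks. The
#' default confidence interval uses the DeLong placement variance; a
#' stratified bootstrap (resampling cases and controls separately,
#' percentile interval) is available as an alternative.
#'
#' @param scores numeric vector.
#' @param outcome binary 0/1 vector; both classes must be present.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param conf_level confidence level (default 0.95).
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed seed for the bootstrap.
#' @return list with `auc`, `ci` (length-2 vector), `se` (DeLong only),
#'   `ci_method`, `n_cases`, `n_controls`.
#' @export
compute_auc_ci <- function(scores, outcome,
                           ci_method = c("delong", "bootstrap"),
                           conf_level = 0.95, n_boot = 2000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  check_two_classes(outcome)
  cases <- scores[outcome == 1L]
  controls <- scores[outcome == 0L]
  n1 <- length(cases); n0 <- length(controls)
  auc <- auc_mannwhitney(cases, controls)
  alpha <- 1 - conf_level
  if (ci_method == "delong") {
    r_all <- rank(c(cases, controls))
    v10 <- (r_all[seq_len(n1)] - rank(cases)) / n0
    v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(controls)) / n1
    s2 <- stats::var(v10) / n1 + stats::var(v01) / n0
    se <- sqrt(s2)
    z <- stats::qnorm(1 - alpha / 2)
    ci <- pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
  } else {
    boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      auc_mannwhitney(sample(cases, n1, replace = TRUE),
                      sample(controls, n0, replace = TRUE))
    }, numeric(1)))
    ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 6))
    se <- stats::sd(boot)
  }
  list(auc = auc, ci = ci, se = se, ci_method = ci_method,
       n_cases = n1, n_controls = n0)
}

auc_mannwhitney <- function(cases, controls) {
  n1 <- length(cases); n0 <- length(controls)
  r <- rank(c(cases, controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Recalibration intercept, slope, and grouped calibration curve
#'
#' Fits the logistic recalibration model `outcome ~ logit(predicted)`: a
#' slope of 1 and intercept of 0 indicate perfect calibration; slopes below
#' 1 indicate predictions that are too extreme (overfitting). The curve bins
#' participants into `n_bins` equal-count groups of predicted risk and
#' reports mean predicted probability against observed event proportion.
#'
#' @param predicted_probs predicted probabilities, strictly inside (0, 1);
#'   values at the boundary are clipped to `epsilon` with a warning.
#' @param outcome binary 0/1 vector.
#' @param n_bins number of quantile bins (default 10, i.e. deciles of risk).
#' @param epsilon clipping bound for boundary probabilities.
#' @return list with `calib_intercept`, `calib_slope`, their standard errors,
#'   and `calib_curve` (data.frame: `bin`, `mean_predicted`,
#'   `observed_proportion`, `n`).
#' @export
calibration_assess <- function(predicted_probs, outcome, n_bins = 10L,
                               epsilon = 1e-8) {
  check_two_classes(outcome)
  if (any(predicted_probs <= 0) || any(predicted_probs >= 1)) {
    warning("predicted probabilities at or beyond 0/1 clipped to epsilon")
    predicted_probs <- pmin(pmax(predicted_probs, epsilon), 1 - epsilon)
  }
  lp <- stats::qlogis(predicted_probs)
  if (stats::var(lp) == 0) {
    stop("degenerate input: constant predictions, calibration slope undefined")
  }
  fit <- suppressWarnings(stats::glm(outcome ~ lp, family = stats::binomial()))
  se <- sqrt(diag(stats::vcov(fit)))
  breaks <- unique(stats::quantile(predicted_probs,
                                   probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(predicted_probs, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  curve <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    idx <- bin == b
    data.frame(bin = b, mean_predicted = mean(predicted_probs[idx]),
               observed_proportion = mean(outcome[idx]), n = sum(idx))
  }))
  list(calib_intercept = unname(stats::coef(fit)[1]),
       calib_slope = unname(stats::coef(fit)[2]),
       se_intercept = unname(se[1]), se_slope = unname(se[2]),
       calib_curve = curve)
}

#' Sensitivity and specificity of a binary classification
#'
#' @param high_risk binary 0/1 classification vector.
#' @param outcome binary 0/1 outcome vector of the same length.
#' @return list with `sensitivity`, `specificity`, and the 2x2 counts `tp`,
#'   `fn`, `tn`, `fp`; an undefined proportion (empty denominator) is
#'   returned as `NA` with a warning.
#' @export
confusion_metrics <- function(high_risk, outcome) {
  if (length(high_risk) == 0L) stop("empty input")
  if (length(high_risk) != length(outcome)) stop("length mismatch")
  tp <- sum(high_risk == 1L & outcome == 1L)
  fn <- sum(high_risk == 0L & outcome == 1L)
  tn <- sum(high_risk == 0L & outcome == 0L)
  fp <- sum(high_risk == 1L & outcome == 0L)
  sens <- if (tp + fn == 0L) { warning("no events: sensitivity undefined"); NA_real_ } else tp / (tp + fn)
  spec <- if (tn + fp == 0L) { warning("no non-events: specificity undefined"); NA_real_ } else tn / (tn + fp)
  list(sensitivity = sens, specificity = spec, tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Odds ratio with a Wald confidence interval
#'
#' `OR = (a d) / (b c)` from the 2x2 table of exposure by outcome, with
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` as the interval. Zero
#' cells get the Haldane--Anscombe 0.5 correction, with a warning.
#'
#' @param exposed binary 0/1 exposure vector (e.g. high-risk classification).
#' @param outcome binary 0/1 outcome vector.
#' @param conf_level confidence level (default 0.95).
#' @return list with `or`, `ci`, and the table cells `a` (exposed, event),
#'   `b` (exposed, no event), `c` (unexposed, event), `d` (unexposed, no
#'   event).
#' @export
odds_ratio <- function(exposed, outcome, conf_level = 0.95) {
  if (length(exposed) == 0L) stop("empty input")
  if (length(exposed) != length(outcome)) stop("length mismatch")
  a <- sum(exposed == 1L & outcome == 1L)
  b <- sum(exposed == 1L & outcome == 0L)
  cc <- sum(exposed == 0L & outcome == 1L)
  d <- sum(exposed == 0L & outcome == 0L)
  cells <- c(a = a, b = b, c = cc, d = d)
  if (any(cells == 0L)) {
    warning("zero cell in 2x2 table: Haldane-Anscombe 0.5 correction applied")
    cells <- cells + 0.5
  }
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * z * se)
  list(or = unname(or), ci = unname(ci), a = a, b = b, c = cc, d = d)
}

#' Descriptive comparison of characteristics by outcome group
#'
#' Builds a "Table 1": for each categorical characteristic, counts and
#' column percentages within the outcome and no-outcome groups, plus a
#' Pearson chi-square p-value (no continuity correction) for the
#' association. Percentage denominators are the full group totals (missing
#' included), so the explicit `Missing` row completes each characteristic
#' to 100%; the Missing level is by default also a category of the test.
#'
#' @param x a `cohort`, or any data.frame with an `outcome` column.
#' @param characteristics named list; each element is either a length-1
#'   character naming a binary item column of `x` (displayed as Yes/No), or
#'   a vector of per-participant categorical values (`NA` = missing).
#' @param chisq_include_missing include the Missing category in the test.
#' @param show_missing add an explicit Missing level when missing values
#'   occur.
#' @return data.frame with columns `characteristic`, `level`, `n_outcome`,
#'   `pct_outcome`, `n_no_outcome`, `pct_no_outcome`, `chisq_p` (repeated
#'   across the rows of a characteristic; `NA` when fewer than two observed
#'   levels).
#' @export
table_one <- function(x, characteristics, chisq_include_missing = TRUE,
                      show_missing = TRUE) {
  outcome <- x$outcome
  n1 <- sum(outcome == 1L)
  n0 <- sum(outcome == 0L)
  rows <- lapply(names(characteristics), function(nm) {
    ch <- characteristics[[nm]]
    v <- if (is.character(ch) && length(ch) == 1L && ch %in% names(x)) {
      factor(ifelse(is.na(x[[ch]]), NA, ifelse(x[[ch]] == 1L, "Yes", "No")),
             levels = c("Yes", "No"))
    } else {
      if (length(ch) != length(outcome)) {
        stop("characteristic '", nm, "' has wrong length")
      }
      if (is.factor(ch)) ch else factor(ch)
    }
    lv <- levels(v)
    tab1 <- table(factor(v[outcome == 1L], levels = lv))
    tab0 <- table(factor(v[outcome == 0L], levels = lv))
    if (show_missing && anyNA(v)) {
      tab1 <- c(tab1, Missing = sum(is.na(v[outcome == 1L])))
      tab0 <- c(tab0, Missing = sum(is.na(v[outcome == 0L])))
      lv <- c(lv, "Missing")
    }
    test_lv <- if (chisq_include_missing) lv else setdiff(lv, "Missing")
    m <- rbind(tab1[test_lv], tab0[test_lv])
    m <- m[, colSums(m) > 0, drop = FALSE]
    p <- if (ncol(m) < 2L) NA_real_ else
      suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
    data.frame(
      characteristic = nm, level = lv,
      n_outcome = as.integer(tab1), pct_outcome = 100 * as.integer(tab1) / n1,
      n_no_outcome = as.integer(tab0), pct_no_outcome = 100 * as.integer(tab0) / n0,
      chisq_p = p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full validation report for a score on one cohort
#'
#' Bundles discrimination (AUC with CI), calibration (when predicted
#' probabilities are supplied), threshold metrics at the high-risk cutoff,
#' and the odds ratio of high-risk classification versus the outcome.
#'
#' @param scores integer score vector.
#' @param outcome binary 0/1 outcome vector.
#' @param cutoff high-risk threshold.
#' @param predicted_probs optional predicted probabilities (e.g. from a
#'   development-set score model) for calibration assessment.
#' @param ci_method AUC CI method, see [compute_auc_ci()].
#' @param n_bins calibration-curve bins.
#' @return object of class `validation_report`: list with `auc`, `auc_ci`,
#'   `calib_intercept`, `calib_slope`, `calib_curve`, `sensitivity`,
#'   `specificity`, `or_high`, `or_ci`, `n`, `n_events`, `cutoff`.
#' @export
build_validation_report <- function(scores, outcome, cutoff,
                                    predicted_probs = NULL,
                                    ci_method = "delong", n_bins = 10L) {
  auc <- compute_auc_ci(scores, outcome, ci_method = ci_method)
  high <- classify_high_risk(scores, cutoff)
  cm <- confusion_metrics(high, outcome)
  or <- odds_ratio(high, outcome)
  calib <- if (is.null(predicted_probs)) {
    list(calib_intercept = NA_real_, calib_slope = NA_real_, calib_curve = NULL)
  } else {
    calibration_assess(predicted_probs, outcome, n_bins = n_bins)
  }
  structure(list(
    auc = auc$auc, auc_ci = auc$ci, ci_method = ci_method,
    calib_intercept = calib$calib_intercept, calib_slope = calib$calib_slope,
    calib_curve = calib$calib_curve,
    sensitivity = cm$sensitivity, specificity = cm$specificity,
    or_high = or$or, or_ci = or$ci,
    n = length(outcome), n_events = sum(outcome == 1L),
    cutoff = as.integer(cutoff)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n = %d (%d events)\n", x$n, x$n_events))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f, %s)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$ci_method))
  if (!is.na(x$calib_slope)) {
    cat(sprintf("  calibration intercept %.3f, slope %.3f\n",
                x$calib_intercept, x$calib_slope))
  }
  cat(sprintf("  cutoff >= %d: sensitivity %.1f%%, specificity %.1f%%, OR %.2f (%.2f-%.2f)\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity,
              x$or_high, x$or_ci[1], x$or_ci[2]))
  invisible(x)
}

#' Plot a calibration curve
#'
#' Observed event proportion against mean predicted risk per bin, with the
#' 45-degree perfect-calibration reference and an annotation of the
#' recalibration intercept, slope, and c-statistic. Requires ggplot2.
#'
#' @param report a `validation_report` with a calibration curve.
#' @param xlim x/y axis limit (default 0.45).
#' @return a ggplot object.
#' @export
plot_calibration <- function(report, xlim = 0.45) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  curve <- report$calib_curve
  if (is.null(curve)) stop("report has no calibration curve")
  ggplot2::ggplot(curve, ggplot2::aes(x = mean_predicted, y = observed_proportion)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red", linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = n), show.legend = FALSE) +
    ggplot2::coord_cartesian(xlim = c(0, xlim), ylim = c(0, xlim)) +
    ggplot2::annotate("text", x = 0.02, y = xlim * 0.95, hjust = 0,
                      label = sprintf("intercept %.2f\nslope %.2f\nc-statistic %.2f",
                                      report$calib_intercept, report$calib_slope,
                                      report$auc)) +
    ggplot2::labs(x = "Predicted probability", y = "Observed proportion") +
    ggplot2::theme_minimal()
}
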