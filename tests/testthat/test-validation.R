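test_that("two-group score logistic fit matches the closed form", {
  # groups at scores 0 and 4 with event rates 0.2 and 0.5: the fitted slope
  # is (logit .5 - logit .2) / 4 because the two-point fit is saturated
  outcome <- c(rep(1L, 20), rep(0L, 80), rep(1L, 50), rep(0L, 50))
  scores <- rep(c(0L, 4L), each = 100)
  fit <- fit_score_logit(scores, outcome)
  expect_equal(fit$beta_per_point, (qlogis(0.5) - qlogis(0.2)) / 4,
               tolerance = 1e-6)
  expect_equal(fit$intercept, qlogis(0.2), tolerance = 1e-6)
})

test_that("score logistic fit rejects degenerate inputs", {
  expect_error(fit_score_logit(1:10, rep(0L, 10)), "both")
  sep <- c(rep(0L, 20), rep(1L, 20))
  expect_error(fit_score_logit(c(rep(1L, 20), rep(10L, 20)), sep), "separation")
})

test_that("AUC equals the all-pairs Mann-Whitney oracle and handles edge cases", {
  perfect <- compute_auc_ci(c(rep(10, 5), rep(1, 5)), rep(c(1L, 0L), each = 5))
  expect_equal(perfect$auc, 1)
  ties <- compute_auc_ci(rep(3, 10), rep(c(1L, 0L), 5))
  expect_equal(ties$auc, 0.5)

  set.seed(61)
  for (k in 1:10) {
    n <- sample(10:40, 1)
    s <- sample(0:15, n, replace = TRUE)
    y <- c(0L, 1L, rbinom(n - 2, 1, 0.4))
    got <- compute_auc_ci(s, y)
    expect_equal(got$auc, oracle_auc(s, y), tolerance = 1e-12)
    expect_lte(got$ci[1], got$auc)
    expect_gte(got$ci[2], got$auc)
    # rank statistic: invariant under strictly increasing transforms
    expect_equal(compute_auc_ci(exp(s / 3) + s, y)$auc, got$auc)
  }
  expect_error(compute_auc_ci(1:5, rep(1L, 5)), "both")
})

test_that("DeLong interval agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  s <- rnorm(150) + rep(c(0, 0.8), times = c(100, 50))
  y <- rep(c(0L, 1L), times = c(100, 50))
  got <- compute_auc_ci(s, y, ci_method = "delong")
  ref <- suppressMessages(pROC::ci.auc(pROC::roc(y, s, quiet = TRUE), method = "delong"))
  expect_equal(got$auc, as.numeric(ref[2]), tolerance = 1e-10)
  # pROC truncates differently at the boundary; compare the raw interval width
  expect_equal(got$ci, as.numeric(ref[c(1, 3)]), tolerance = 1e-6)
})

test_that("bootstrap AUC interval brackets the point estimate", {
  set.seed(63)
  s <- rnorm(120) + rep(c(0, 1), each = 60)
  y <- rep(c(0L, 1L), each = 60)
  got <- compute_auc_ci(s, y, ci_method = "bootstrap", n_boot = 500L, seed = 9L)
  expect_lte(got$ci[1], got$auc)
  expect_gte(got$ci[2], got$auc)
})

test_that("calibration recovers slope 1 for well-specified predictions", {
  set.seed(64)
  n <- 20000
  p <- plogis(rnorm(n, -1.7, 0.8))
  y <- rbinom(n, 1, p)
  cal <- calibration_assess(p, y)
  expect_lt(abs(cal$calib_slope - 1), 3 * cal$se_slope)
  expect_lt(abs(cal$calib_intercept), 3 * cal$se_intercept)
  expect_equal(nrow(cal$calib_curve), 10)
  expect_equal(sum(cal$calib_curve$n), n)
})

test_that("halving the logit doubles the recalibration slope", {
  set.seed(65)
  n <- 20000
  lp <- rnorm(n, -1.7, 0.9)
  y <- rbinom(n, 1, plogis(lp))
  cal <- calibration_assess(plogis(lp / 2), y)
  expect_lt(abs(cal$calib_slope - 2), 3 * cal$se_slope)
})

test_that("calibration flags degenerate and boundary predictions", {
  y <- rep(c(0L, 1L), 10)
  expect_error(calibration_assess(rep(0.3, 20), y), "constant")
  expect_warning(calibration_assess(c(0, runif(18, 0.2, 0.8), 1), y), "clipped")
})

test_that("confusion metrics reproduce hand-computed rates", {
  y <- rep(c(1L, 0L), each = 10)
  expect_equal(confusion_metrics(y, y)[c("sensitivity", "specificity")],
               list(sensitivity = 1, specificity = 1))
  expect_equal(confusion_metrics(1L - y, y)[c("sensitivity", "specificity")],
               list(sensitivity = 0, specificity = 0))

  # 23 true positives / 100 events, 90 true negatives / 100 non-events
  high <- c(rep(1L, 23), rep(0L, 77), rep(0L, 90), rep(1L, 10))
  outc <- rep(c(1L, 0L), each = 100)
  cm <- confusion_metrics(high, outc)
  expect_equal(cm$sensitivity, 0.23)
  expect_equal(cm$specificity, 0.90)
  expect_error(confusion_metrics(integer(0), integer(0)), "empty")
})

test_that("odds ratios follow the cross-product formula", {
  mk <- function(a, b, c, d) {
    list(exposed = rep(c(1L, 1L, 0L, 0L), c(a, b, c, d)),
         outcome = rep(c(1L, 0L, 1L, 0L), c(a, b, c, d)))
  }
  v <- mk(20, 10, 5, 40)
  expect_equal(odds_ratio(v$exposed, v$outcome)$or, 16)
  v2 <- mk(10, 10, 10, 10)
  or2 <- odds_ratio(v2$exposed, v2$outcome)
  expect_equal(or2$or, 1)
  expect_lt(or2$ci[1], 1); expect_gt(or2$ci[2], 1)

  set.seed(66)
  for (k in 1:10) {
    cells <- sample(5:60, 4)
    v3 <- mk(cells[1], cells[2], cells[3], cells[4])
    got <- odds_ratio(v3$exposed, v3$outcome)
    want_or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    want_se <- sqrt(sum(1 / cells))
    expect_equal(got$or, want_or)
    expect_equal(got$ci, exp(log(want_or) + c(-1, 1) * qnorm(0.975) * want_se))
  }
  v4 <- mk(5, 0, 3, 7)
  expect_warning(or4 <- odds_ratio(v4$exposed, v4$outcome), "Haldane")
  expect_true(is.finite(or4$or))
})

test_that("table_one reports group percentages over full group denominators", {
  # identical distributions in both groups -> chi-square p of 1
  v <- rep(c("a", "b"), 50)
  x <- data.frame(outcome = rep(c(1L, 0L), each = 50))
  t1 <- table_one(x, list(char = rep(c("a", "b"), 50)))
  expect_equal(unique(t1$chisq_p), 1)
  expect_equal(sum(t1$pct_outcome), 100)
  expect_equal(sum(t1$pct_no_outcome), 100)
})

test_that("table_one chi-square matches the textbook statistic", {
  set.seed(67)
  v <- sample(c("x", "y", "z"), 300, replace = TRUE)
  y <- rbinom(300, 1, ifelse(v == "x", 0.4, 0.2))
  t1 <- table_one(data.frame(outcome = y), list(char = v))
  m <- rbind(table(v[y == 1]), table(v[y == 0]))
  stat <- oracle_chisq_stat(m)
  expect_equal(unique(t1$chisq_p),
               pchisq(stat, df = (nrow(m) - 1) * (ncol(m) - 1), lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("table_one handles binary items, missing rows, and one-level inputs", {
  def <- tiny_definition(weights = c(1L, 1L), cutoff = 1L)
  mat <- rbind(c(1L, 1L), c(0L, 1L), c(NA, 1L), c(1L, 1L))
  colnames(mat) <- def$item_id
  x <- tiny_cohort(mat, outcome = c(1L, 1L, 0L, 0L))
  t1 <- table_one(x, list(smoking = "pred_01", always = "pred_02"))
  smoking <- t1[t1$characteristic == "smoking", ]
  expect_equal(smoking$level, c("Yes", "No", "Missing"))
  expect_equal(smoking$pct_outcome, c(50, 50, 0))
  expect_equal(sum(smoking$pct_no_outcome), 100)
  expect_true(is.na(t1$chisq_p[t1$characteristic == "always"][1]))
})

test_that("validation report bundles discrimination, calibration and threshold metrics", {
  set.seed(68)
  n <- 800
  s <- rpois(n, 6)
  y <- rbinom(n, 1, plogis(-2.2 + 0.1 * s))
  fit <- fit_score_logit(s, y)
  pred <- plogis(fit$intercept + fit$beta_per_point * s)
  rep <- build_validation_report(s, y, cutoff = 10L, predicted_probs = pred)
  expect_s3_class(rep, "validation_report")
  expect_gte(rep$auc, 0.5)
  expect_true(rep$auc_ci[1] <= rep$auc && rep$auc <= rep$auc_ci[2])
  expect_equal(rep$n, n)
  expect_equal(rep$n_events, sum(y))
  expect_true(rep$or_high > 0)
  expect_output(print(rep), "AUC")
})
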