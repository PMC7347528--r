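test_that("heuristic shrinkage follows the chi-square formula exactly", {
  expect_equal(heuristic_shrinkage(50, 51), 0)
  expect_equal(heuristic_shrinkage(100, 51), 0.5)
  # algebraic inversion: the chi-square that yields 0.45 at 43 df
  chi2 <- (43 - 1) / (1 - 0.45)
  expect_equal(heuristic_shrinkage(chi2, 43), 0.45)
  expect_error(heuristic_shrinkage(0, 10), "positive")
  expect_error(heuristic_shrinkage(-5, 10), "positive")

  set.seed(71)
  for (k in 1:20) {
    chi2 <- runif(1, 1, 200); df <- sample(2:60, 1)
    s <- heuristic_shrinkage(chi2, df)
    expect_equal(s, (chi2 - (df - 1)) / chi2)
    expect_lte(s, 1)
    expect_gt(heuristic_shrinkage(chi2 + 1, df), s)  # increasing in chi2
  }
})

test_that("sign evaluation drops negative multivariable coefficients", {
  none <- sign_check(c(a = 0.4, b = 0.2), c(a = 0.5, b = 0.1))
  expect_equal(none$dropped_counterintuitive, character(0))

  one <- sign_check(c(a = 0.4, b = -0.2, c = 0.1), c(a = 0.5, b = 0.3, c = 0.2))
  expect_equal(one$dropped_counterintuitive, "b")
  expect_equal(one$kept_items, c("a", "c"))
  expect_equal(one$review_required, character(0))

  both <- sign_check(c(a = -0.4), c(a = -0.5))
  expect_equal(both$review_required, "a")
})

test_that("coefficients rescale into non-negative integer points", {
  expect_equal(rescale_to_points(c(x = 0.18), 1, 0.06), c(x = 3L))
  expect_equal(rescale_to_points(c(x = 0), 1, 0.06), c(x = 0L))
  expect_error(rescale_to_points(c(x = 0.2), 0.5, 0), "positive")
  expect_warning(pts <- rescale_to_points(c(x = 0.2, y = 0.4), -0.1, 0.06))
  expect_equal(pts, c(x = 0L, y = 0L))

  set.seed(72)
  for (k in 1:20) {
    b <- rnorm(5, 0.2, 0.4); names(b) <- letters[1:5]
    s <- runif(1, 0.2, 1); ref <- runif(1, 0.03, 0.2)
    nearest <- rescale_to_points(b, s, ref, "nearest")
    floor_m <- rescale_to_points(b, s, ref, "floor")
    expect_equal(nearest, setNames(as.integer(pmax(floor(s * b / ref + 0.5), 0)), names(b)))
    expect_equal(floor_m, setNames(as.integer(pmax(floor(s * b / ref), 0)), names(b)))
    expect_true(all(nearest >= 0L))
  }
})

test_that("screening finds planted predictors and respects eligibility", {
  hits <- 0L
  for (s in 1:20) {
    def <- tiny_definition(weights = rep(2L, 6), cutoff = 4L,
                           trimester = c(rep("first", 5), "second"))
    cfg <- simulation_config(n_participants = 1200L,
                             prevalences = c(0.15, rep(0.2, 5)),
                             outcome_intercept = NULL, target_outcome_rate = 0.16,
                             beta_per_point = 0.1,
                             extra_item_betas = c(pred_01 = 0.8), seed = s)
    x <- generate_cohort(def, cfg)
    res <- screen_candidates(x, def)
    expect_false(res$eligible[res$item_id == "pred_06"])
    expect_true(all(is.na(res$beta[!res$eligible])))
    if (res$is_candidate[res$item_id == "pred_01"]) hits <- hits + 1L
  }
  expect_gte(hits, 16L)  # planted effect of 0.8 log-odds is found nearly always
})

test_that("a permissive entry threshold admits every estimable eligible item", {
  def <- tiny_definition(weights = rep(2L, 4), cutoff = 2L)
  cfg <- simulation_config(n_participants = 600L, prevalences = 0.3,
                           outcome_intercept = -1.5, beta_per_point = 0.1,
                           seed = 4L)
  x <- generate_cohort(def, cfg)
  res <- screen_candidates(x, def, p_enter = 1.0)
  expect_true(all(res$is_candidate[res$eligible & res$estimable]))
})

test_that("multiparous-only items are screened within multiparous women", {
  # the item predicts the outcome in multiparous women only; full-cohort
  # analysis dilutes it, the scoped analysis finds it
  set.seed(77)
  n <- 3000
  parity <- rep(c("multiparous", "nulliparous"), length.out = n)
  def <- tiny_definition(weights = rep(2L, 3), cutoff = 2L,
                         parity_scope = c("multiparous_only", "all", "all"))
  x1 <- rbinom(n, 1, 0.3); x2 <- rbinom(n, 1, 0.3); x3 <- rbinom(n, 1, 0.3)
  lp <- -2 + ifelse(parity == "multiparous", 1.0 * x1, 0)
  y <- rbinom(n, 1, plogis(lp))
  x <- cohort(data.frame(pred_01 = x1, pred_02 = x2, pred_03 = x3),
              outcome = y, parity = parity)
  res <- screen_candidates(x, def)
  expect_equal(res$subset[res$item_id == "pred_01"], "multiparous")
  expect_true(res$is_candidate[res$item_id == "pred_01"])
})

test_that("backward elimination applies the drop-largest-p rule", {
  set.seed(78)
  def <- tiny_definition(weights = rep(2L, 4), cutoff = 2L)
  cfg <- simulation_config(n_participants = 1500L, prevalences = 0.25,
                           outcome_intercept = NULL, target_outcome_rate = 0.2,
                           beta_per_point = 0.08,
                           extra_item_betas = c(pred_01 = 0.7, pred_02 = 0.6),
                           seed = 79L)
  x <- generate_cohort(def, cfg)

  # single noise candidate with a large p is eliminated
  one <- backward_eliminate(x, def, "pred_04")
  if (length(one$selected_items) == 0L) {
    expect_equal(nrow(one$elimination_trace), 1L)
  }

  # strong candidates all below the threshold survive together
  strong <- backward_eliminate(x, def, c("pred_01", "pred_02"))
  expect_setequal(strong$selected_items, c("pred_01", "pred_02"))
  expect_true(all(strong$wald_p <= 0.20))

  # and a mixed 3-candidate set matches the independent glm-based trace
  for (s in 1:5) {
    cfg2 <- simulation_config(n_participants = 800L, prevalences = 0.25,
                              outcome_intercept = NULL, target_outcome_rate = 0.2,
                              beta_per_point = 0.08,
                              extra_item_betas = c(pred_01 = 0.6), seed = 80L + s)
    x2 <- generate_cohort(def, cfg2)
    cands <- c("pred_01", "pred_02", "pred_03")
    got <- backward_eliminate(x2, def, cands)
    want <- oracle_backward(x2, def, cands)
    expect_setequal(got$selected_items, want)
  }
})

test_that("empty candidate sets return the score-only model", {
  def <- tiny_definition(weights = rep(2L, 3), cutoff = 2L)
  cfg <- simulation_config(n_participants = 500L, prevalences = 0.3,
                           outcome_intercept = -1.5, beta_per_point = 0.15,
                           seed = 81L)
  x <- generate_cohort(def, cfg)
  expect_message(res <- backward_eliminate(x, def, character(0)), "score-only")
  expect_equal(res$selected_items, character(0))
  expect_gt(res$model_chi2, 0)
  expect_gt(res$beta_score, 0)
})

test_that("updated scores add non-negative points on top of the base score", {
  def <- tiny_definition(weights = c(1L, 2L, 3L), cutoff = 3L)
  upd <- updated_scorecard(def, c(pred_01 = 2L, pred_03 = 1L))
  mat <- rbind(c(1L, 0L, 1L), c(0L, 1L, 0L), c(1L, 1L, NA))
  colnames(mat) <- def$item_id
  x <- tiny_cohort(mat)
  base <- compute_cumulative_score(x, def)
  got <- compute_updated_score(x, upd)
  expect_equal(got, base + c(2L + 1L, 0L, 2L))
  expect_true(all(got >= base))

  repl <- updated_scorecard(def, c(pred_01 = 3L), mode = "replace")
  expect_equal(compute_updated_score(x, repl), base + c(2L, 0L, 2L))

  expect_error(updated_scorecard(def, c(nope = 1L)), "unknown")
})

test_that("run_update returns the base scorecard under a null outcome", {
  def <- tiny_definition(weights = rep(2L, 5), cutoff = 3L)
  cfg <- simulation_config(n_participants = 900L, prevalences = 0.3,
                           outcome_intercept = NULL, target_outcome_rate = 0.25,
                           beta_per_point = 0.12, seed = 82L)
  x <- generate_cohort(def, cfg)
  res <- run_update(x, def)
  expect_true(all(res$model$additional_points >= 0L))
  expect_lte(length(res$model$candidates), 3L)  # ~20% null candidate rate
  upd_scores <- compute_updated_score(x, res$scorecard)
  base_scores <- compute_cumulative_score(x, def)
  expect_true(all(upd_scores >= base_scores))
})

test_that("run_update is deterministic and traces its provenance", {
  sc <- counterintuitive_scenario(seed = 5L, n = 2000L)
  x <- generate_cohort(sc$definition, sc$config)
  r1 <- run_update(x, sc$definition)
  r2 <- run_update(x, sc$definition)
  expect_identical(r1$model$additional_points, r2$model$additional_points)
  expect_identical(r1$model$shrinkage, r2$model$shrinkage)
  expect_equal(r1$model$df_considered,
               7L + 1L + length(r1$model$selected_items))
  expect_equal(r1$model$shrinkage,
               (r1$model$model_chi2 - (r1$model$df_considered - 1)) /
                 r1$model$model_chi2)
  expect_true(all(names(r1$model$additional_points) %in%
                    setdiff(r1$model$selected_items,
                            r1$model$dropped_counterintuitive)))
  expect_output(print(r1$model), "shrinkage")
})

test_that("run_update refuses incomplete development data", {
  def <- tiny_definition(weights = rep(1L, 2), cutoff = 1L)
  mat <- rbind(c(1L, NA), c(0L, 1L), c(1L, 1L), c(0L, 0L))
  colnames(mat) <- def$item_id
  x <- tiny_cohort(mat)
  expect_error(run_update(x, def), "impute")
})
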