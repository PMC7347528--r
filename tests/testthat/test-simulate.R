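test_that("generated definitions hit the requested weight total exactly", {
  def <- generate_definition(50L, 26L, 98L, seed = 1L)
  expect_equal(max_possible_score(def), 98L)
  expect_equal(sum(def$role == "predictor"), 50L)
  expect_equal(sum(def$role == "awareness"), 26L)

  forced <- generate_definition(1L, 0L, 3L, seed = 99L)
  expect_equal(forced$points, 3L)

  d1 <- generate_definition(10L, 0L, 20L, seed = 7L)
  d2 <- generate_definition(10L, 0L, 20L, seed = 7L)
  expect_identical(as.data.frame(d1), as.data.frame(d2))

  expect_error(generate_definition(5L, 0L, 16L, seed = 1L), "infeasible")
  expect_error(generate_definition(5L, 0L, 4L, seed = 1L), "infeasible")
})

test_that("cohort generation respects prevalences, seed, and outcome model", {
  def <- tiny_definition(weights = rep(2L, 4), cutoff = 2L)
  cfg <- simulation_config(n_participants = 200L, prevalences = 0,
                           outcome_intercept = 0, beta_per_point = 0, seed = 3L)
  x <- generate_cohort(def, cfg)
  expect_true(all(response_matrix(x, predictor_items(def)) == 0L))
  expect_equal(compute_cumulative_score(x, def), rep(0L, 200))

  x2 <- generate_cohort(def, cfg)
  expect_identical(as.data.frame(x), as.data.frame(x2))
})

test_that("marginal outcome rate matches the configured intercept", {
  def <- tiny_definition(weights = rep(1L, 5), cutoff = 2L)
  cfg <- simulation_config(n_participants = 50000L, prevalences = 0.1,
                           outcome_intercept = qlogis(0.16),
                           beta_per_point = 0, seed = 5L)
  x <- generate_cohort(def, cfg)
  se <- sqrt(0.16 * 0.84 / 50000)
  expect_lt(abs(mean(x$outcome) - 0.16), 3 * se)
})

test_that("outcome prevalence is monotone in the intercept", {
  def <- tiny_definition(weights = rep(1L, 3), cutoff = 1L)
  rates <- vapply(c(-3, -1, 1), function(ic) {
    cfg <- simulation_config(n_participants = 4000L, prevalences = 0.2,
                             outcome_intercept = ic, beta_per_point = 0.05,
                             seed = 8L)
    mean(generate_cohort(def, cfg)$outcome)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("exchangeable latent correlation shows up in pairwise tetrachoric terms", {
  def <- tiny_definition(weights = rep(1L, 6), cutoff = 1L)
  cfg <- simulation_config(n_participants = 2000L, prevalences = 0.3,
                           correlation = 0.3, outcome_intercept = -2,
                           beta_per_point = 0, seed = 13L)
  x <- generate_cohort(def, cfg)
  m <- response_matrix(x, predictor_items(def))
  pairs <- utils::combn(ncol(m), 2)
  rho <- mean(apply(pairs, 2, function(ij) approx_tetrachoric(m[, ij[1]], m[, ij[2]])))
  expect_lt(abs(rho - 0.3), 0.1)
})

test_that("score regression recovers the generating per-point coefficient", {
  def <- tiny_definition(weights = rep(2L, 8), cutoff = 4L)
  cfg <- simulation_config(n_participants = 50000L, prevalences = 0.25,
                           correlation = 0.1, outcome_intercept = -2.4,
                           beta_per_point = 0.06, seed = 17L)
  x <- generate_cohort(def, cfg)
  fit <- fit_score_logit(compute_cumulative_score(x, def), x$outcome)
  expect_lt(abs(fit$beta_per_point - 0.06), 3 * fit$se_beta)

  # and a null coefficient when the score carries no information
  cfg0 <- simulation_config(n_participants = 50000L, prevalences = 0.25,
                            outcome_intercept = qlogis(0.16),
                            beta_per_point = 0, seed = 18L)
  x0 <- generate_cohort(def, cfg0)
  fit0 <- fit_score_logit(compute_cumulative_score(x0, def), x0$outcome)
  expect_lt(abs(fit0$beta_per_point), 3 * fit0$se_beta)
})

test_that("missingness injection hits the participant rate and spares the outcome", {
  def <- tiny_definition(weights = rep(1L, 10), cutoff = 2L)
  cfg <- simulation_config(n_participants = 20000L, prevalences = 0.2,
                           outcome_intercept = qlogis(0.16), beta_per_point = 0,
                           missing_participant_rate = 0.07, seed = 21L)
  x <- generate_cohort(def, cfg)
  expect_identical(inject_missingness(x, simulation_config(
    n_participants = 10L, prevalences = 0.1, missing_participant_rate = 0,
    seed = 1L)), x)

  xm <- inject_missingness(x, cfg, def)
  realized <- participant_missing_rate(xm, def)
  se <- sqrt(0.07 * 0.93 / 20000)
  expect_lt(abs(realized - 0.07), 3 * se)
  expect_false(anyNA(xm$outcome))
  expect_false(anyNA(xm$parity))
})

test_that("MAR mechanism concentrates missingness on participants with the outcome", {
  def <- tiny_definition(weights = rep(1L, 10), cutoff = 2L)
  cfg <- simulation_config(n_participants = 30000L, prevalences = 0.2,
                           outcome_intercept = qlogis(0.3), beta_per_point = 0,
                           missing_participant_rate = 0.10,
                           missing_mechanism = "MAR_on_outcome",
                           mar_odds_multiplier = 3, seed = 23L)
  x <- generate_cohort(def, cfg)
  xm <- inject_missingness(x, cfg, def)
  has_miss <- rowSums(is.na(response_matrix(xm, predictor_items(def)))) > 0
  rate1 <- mean(has_miss[xm$outcome == 1L])
  rate0 <- mean(has_miss[xm$outcome == 0L])
  expect_gt(rate1, rate0 * 1.5)
  expect_lt(abs(mean(has_miss) - 0.10), 3 * sqrt(0.1 * 0.9 / 30000))
})

test_that("temporal split partitions the cohort in enrolment order", {
  def <- tiny_definition(weights = rep(1L, 2), cutoff = 1L)
  mk <- function(n) tiny_cohort(matrix(0L, n, 2, dimnames = list(NULL, def$item_id)))
  s10 <- assign_temporal_split(mk(10), 0.5)
  expect_equal(table(s10$split)[["development"]], 5L)
  expect_equal(s10$split, rep(c("development", "validation"), each = 5))

  s100 <- assign_temporal_split(mk(100), 0.99)
  expect_equal(sum(s100$split == "development"), 99L)
  expect_true(all(s100$split %in% c("development", "validation")))

  expect_error(assign_temporal_split(mk(10), 0), "configuration")
  expect_error(assign_temporal_split(mk(10), 1), "configuration")
  expect_error(assign_temporal_split(s10, 0.5), "already")
})

test_that("bundled scenarios load and regenerate deterministically", {
  sc <- hp4all_scenario(seed = 4L)
  expect_equal(sc$config$n_participants, 1752L)
  expect_equal(max_possible_score(sc$definition), 98L)
  expect_equal(length(sc$config$prevalences), 50L)
  expect_gte(sum(sc$config$prevalences < 0.02), 10L)
  x1 <- generate_cohort(sc$definition, sc$config)
  x2 <- generate_cohort(sc$definition, sc$config)
  expect_identical(as.data.frame(x1), as.data.frame(x2))
})
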