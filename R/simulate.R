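#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic scorecard definition
#'
#' Draws predictor weights in 1--3 that sum exactly to `target_max_score`
#' (all weights start at 1 and the remaining points are spread uniformly at
#' random over items still below 3), and appends unscored awareness items.
#' Optionally marks some predictors as second-trimester or multiparous-only.
#'
#' @param n_predictors number of scored predictor items.
#' @param n_awareness number of unscored awareness items.
#' @param target_max_score desired maximum cumulative score; feasible iff
#'   `n_predictors <= target_max_score <= 3 * n_predictors`.
#' @param seed integer seed (same seed, same definition).
#' @param n_second_trimester predictors assessed in the second trimester.
#' @param n_multiparous_only first-trimester predictors (prior-pregnancy
#'   characteristics) scored for multiparous women only.
#' @param cutoff high-risk threshold.
#' @return a `scorecard_definition`.
#' @export
generate_definition <- function(n_predictors, n_awareness, target_max_score,
                                seed, n_second_trimester = 0L,
                                n_multiparous_only = 0L,
                                cutoff = min(16L, target_max_score)) {
  if (target_max_score < n_predictors || target_max_score > 3L * n_predictors) {
    stop("infeasible target_max_score: need n_predictors <= target <= 3*n_predictors")
  }
  if (n_second_trimester + n_multiparous_only > n_predictors) {
    stop("more scoped predictors requested than predictors")
  }
  with_seed(seed, {
    w <- rep(1L, n_predictors)
    extra <- target_max_score - n_predictors
    while (extra > 0L) {
      open <- which(w < 3L)
      pick <- if (length(open) == 1L) open else sample(open, 1L)
      w[pick] <- w[pick] + 1L
      extra <- extra - 1L
    }
    trimester <- rep("first", n_predictors)
    if (n_second_trimester > 0L) {
      trimester[sample.int(n_predictors, n_second_trimester)] <- "second"
    }
    parity_scope <- rep("all", n_predictors)
    if (n_multiparous_only > 0L) {
      eligible <- which(trimester == "first")
      parity_scope[sample(eligible, n_multiparous_only)] <- "multiparous_only"
    }
    items <- data.frame(
      item_id = sprintf("pred_%02d", seq_len(n_predictors)),
      label = sprintf("synthetic predictor item %d", seq_len(n_predictors)),
      role = "predictor",
      trimester = trimester,
      parity_scope = parity_scope,
      points = w,
      stringsAsFactors = FALSE
    )
    if (n_awareness > 0L) {
      items <- rbind(items, data.frame(
        item_id = sprintf("aware_%02d", seq_len(n_awareness)),
        label = sprintf("synthetic awareness item %d", seq_len(n_awareness)),
        role = "awareness",
        trimester = "first",
        parity_scope = "all",
        points = 0L,
        stringsAsFactors = FALSE
      ))
    }
    scorecard_definition(items, cutoff = cutoff,
                         version = sprintf("synthetic-seed%d", seed))
  })
}

#' Simulation configuration
#'
#' Bundles every knob of the cohort generator. Binary item responses come
#' from a latent-Gaussian threshold model: each participant draws a latent
#' normal vector with exchangeable correlation `correlation` (optionally
#' overridden for named item pairs via `pair_correlations`), and item j is
#' positive when its latent falls below the quantile of `prevalences[j]`.
#' The outcome is Bernoulli on the logistic scale:
#' `logit p = intercept + beta_per_point * score + sum(extra_item_betas * x)`.
#' If `outcome_intercept` is `NULL`, the intercept is solved so the expected
#' outcome rate over the realized covariates equals `target_outcome_rate`.
#'
#' @param n_participants cohort size.
#' @param prevalences per-predictor positivity probabilities (length = number
#'   of predictor items, in definition order); recycled if scalar.
#' @param correlation exchangeable latent correlation in [0, 1).
#' @param pair_correlations optional data.frame (`item1`, `item2`, `rho`)
#'   overriding the latent correlation for specific predictor pairs.
#' @param outcome_intercept log-odds intercept, or `NULL` to calibrate.
#' @param target_outcome_rate marginal outcome rate used when the intercept
#'   is calibrated (default 0.16).
#' @param beta_per_point log-odds per cumulative score point.
#' @param extra_item_betas named numeric vector of per-item log-odds
#'   deviations beyond the score (items not named get 0).
#' @param multiparous_prob probability of being multiparous (default 0.543).
#' @param missing_participant_rate target fraction of participants with at
#'   least one missing predictor response.
#' @param missing_mechanism `"MCAR"` or `"MAR_on_outcome"`.
#' @param mar_odds_multiplier odds multiplier on the participant-level
#'   missingness probability when outcome = 1 (MAR mechanism only).
#' @param item_missing_prob per-item missingness probability within an
#'   affected participant (at least one item is always forced missing).
#' @param development_fraction proportion assigned to the development split.
#' @param seed integer seed.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_participants,
                              prevalences,
                              correlation = 0,
                              pair_correlations = NULL,
                              outcome_intercept = NULL,
                              target_outcome_rate = 0.16,
                              beta_per_point = 0.06,
                              extra_item_betas = NULL,
                              multiparous_prob = 0.543,
                              missing_participant_rate = 0,
                              missing_mechanism = c("MCAR", "MAR_on_outcome"),
                              mar_odds_multiplier = 2,
                              item_missing_prob = 0.05,
                              development_fraction = 2 / 3,
                              seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  stopifnot(
    n_participants >= 1L,
    all(prevalences >= 0 & prevalences <= 1),
    correlation >= 0, correlation < 1,
    missing_participant_rate >= 0, missing_participant_rate <= 1,
    development_fraction > 0, development_fraction < 1,
    multiparous_prob >= 0, multiparous_prob <= 1
  )
  structure(list(
    n_participants = as.integer(n_participants),
    prevalences = prevalences,
    correlation = correlation,
    pair_correlations = pair_correlations,
    outcome_intercept = outcome_intercept,
    target_outcome_rate = target_outcome_rate,
    beta_per_point = beta_per_point,
    extra_item_betas = extra_item_betas,
    multiparous_prob = multiparous_prob,
    missing_participant_rate = missing_participant_rate,
    missing_mechanism = missing_mechanism,
    mar_odds_multiplier = mar_odds_multiplier,
    item_missing_prob = item_missing_prob,
    development_fraction = development_fraction,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

latent_correlation_matrix <- function(def_pred, config) {
  p <- length(def_pred)
  sigma <- matrix(config$correlation, p, p)
  diag(sigma) <- 1
  pc <- config$pair_correlations
  if (!is.null(pc) && nrow(pc) > 0L) {
    for (k in seq_len(nrow(pc))) {
      i <- match(pc$item1[k], def_pred)
      j <- match(pc$item2[k], def_pred)
      if (is.na(i) || is.na(j)) {
        stop("pair_correlations names unknown predictor item(s): ",
             pc$item1[k], " / ", pc$item2[k])
      }
      sigma[i, j] <- sigma[j, i] <- pc$rho[k]
    }
  }
  sigma
}

#' Generate a synthetic cohort
#'
#' Draws correlated binary item responses, parity, and a logistic composite
#' outcome as described in [simulation_config()]. Awareness items are drawn
#' independently at a fixed 10% positivity; they never enter the outcome
#' model. The returned cohort has no missing entries and an unassigned split.
#'
#' @param definition a `scorecard_definition`.
#' @param config a `simulation_config`; `prevalences` must match the number
#'   of predictor items.
#' @return a `cohort` with attribute `"true_intercept"` (the intercept
#'   actually used for the outcome model).
#' @export
generate_cohort <- function(definition, config) {
  pred <- predictor_items(definition)
  p <- length(pred)
  prev <- config$prevalences
  if (length(prev) == 1L) prev <- rep(prev, p)
  if (length(prev) != p) {
    stop("configuration error: prevalences has length ", length(prev),
         " but the definition has ", p, " predictors")
  }
  extra <- rep(0, p)
  names(extra) <- pred
  if (!is.null(config$extra_item_betas)) {
    bad <- setdiff(names(config$extra_item_betas), pred)
    if (length(bad) > 0L) {
      stop("configuration error: extra_item_betas names unknown item(s): ",
           paste(bad, collapse = ", "))
    }
    extra[names(config$extra_item_betas)] <- config$extra_item_betas
  }
  n <- config$n_participants
  with_seed(config$seed, {
    sigma <- latent_correlation_matrix(pred, config)
    ch <- tryCatch(chol(sigma), error = function(e) {
      ev <- eigen(sigma, symmetric = TRUE)
      lam <- pmax(ev$values, 1e-8)
      s2 <- ev$vectors %*% (lam * t(ev$vectors))
      d <- sqrt(diag(s2))
      chol(s2 / tcrossprod(d))
    })
    z <- matrix(stats::rnorm(n * p), n, p) %*% ch
    x <- matrix(0L, n, p, dimnames = list(NULL, pred))
    thresh <- stats::qnorm(prev)
    for (j in seq_len(p)) x[, j] <- as.integer(z[, j] < thresh[j])
    w <- definition$points[match(pred, definition$item_id)]
    score <- as.numeric(x %*% w)
    lp_part <- config$beta_per_point * score + as.numeric(x %*% extra)
    a <- config$outcome_intercept
    if (is.null(a)) {
      target <- config$target_outcome_rate
      a <- stats::uniroot(
        function(ic) mean(stats::plogis(ic + lp_part)) - target,
        interval = c(-30, 30), tol = 1e-10
      )$root
    }
    outcome <- stats::rbinom(n, 1L, stats::plogis(a + lp_part))
    parity <- ifelse(stats::runif(n) < config$multiparous_prob,
                     "multiparous", "nulliparous")
    aware <- awareness_items(definition)
    responses <- as.data.frame(x)
    for (j in aware) responses[[j]] <- stats::rbinom(n, 1L, 0.10)
    out <- cohort(responses, outcome = outcome, parity = parity)
    attr(out, "true_intercept") <- a
    out
  })
}

#' Inject missing predictor responses into a complete cohort
#'
#' Selects participants to carry missingness so that the expected fraction of
#' participants with at least one missing predictor equals
#' `missing_participant_rate`; within an affected participant each predictor
#' item goes missing independently with probability `item_missing_prob`, with
#' one item forced missing if none was drawn. Under `"MCAR"` all participants
#' are equally likely to be affected; under `"MAR_on_outcome"` the odds of
#' being affected are multiplied by `mar_odds_multiplier` for participants
#' with the outcome (the base probability is rescaled so the marginal rate is
#' preserved). The outcome, parity, split, and awareness columns are never
#' made missing.
#'
#' @param x a complete `cohort`.
#' @param config a `simulation_config` (fields `missing_participant_rate`,
#'   `missing_mechanism`, `mar_odds_multiplier`, `item_missing_prob`, `seed`).
#' @param definition optional definition restricting missingness to its
#'   predictor items; defaults to columns prefixed `pred_` when absent.
#' @return a `cohort` with `NA` entries among predictor responses.
#' @export
inject_missingness <- function(x, config, definition = NULL) {
  rate <- config$missing_participant_rate
  if (rate < 0 || rate > 1) stop("configuration error: rate outside [0,1]")
  if (rate == 0) return(x)
  items <- if (!is.null(definition)) {
    intersect(predictor_items(definition), item_columns(x))
  } else {
    grep("^pred_", item_columns(x), value = TRUE)
  }
  if (anyNA(response_matrix(x, items))) stop("cohort already has missing entries")
  n <- nrow(x)
  with_seed(config$seed + 1L, {
    if (config$missing_mechanism == "MCAR") {
      p_aff <- rep(rate, n)
    } else {
      mult <- config$mar_odds_multiplier
      f <- function(p0) {
        odds <- p0 / (1 - p0)
        mean(ifelse(x$outcome == 1L, mult * odds / (1 + mult * odds), p0)) - rate
      }
      p0 <- stats::uniroot(f, interval = c(1e-9, 1 - 1e-9), tol = 1e-12)$root
      odds <- p0 / (1 - p0)
      p_aff <- ifelse(x$outcome == 1L, mult * odds / (1 + mult * odds), p0)
    }
    affected <- which(stats::runif(n) < p_aff)
    for (i in affected) {
      gone <- which(stats::runif(length(items)) < config$item_missing_prob)
      if (length(gone) == 0L) gone <- sample.int(length(items), 1L)
      for (j in items[gone]) x[[j]][i] <- NA_integer_
    }
    x
  })
}

#' Assign a temporal development/validation split
#'
#' Mirrors enrolment-date splitting: the first `ceiling(fraction * n)`
#' participants in row (enrolment) order form the development set, the rest
#' the validation set. Set `shuffle = TRUE` to permute enrolment order first
#' (seeded), e.g. to break ties with an ordered generator.
#'
#' @param x a `cohort` with all splits `"unassigned"`.
#' @param development_fraction proportion in (0, 1).
#' @param seed seed for the optional shuffle.
#' @param shuffle permute rows before splitting.
#' @return the `cohort` with `split` filled in; every participant lands in
#'   exactly one split.
#' @export
assign_temporal_split <- function(x, development_fraction, seed = NULL,
                                  shuffle = FALSE) {
  if (development_fraction <= 0 || development_fraction >= 1) {
    stop("configuration error: development_fraction must be in (0,1)")
  }
  if (!all(x$split == "unassigned")) stop("cohort split already assigned")
  n <- nrow(x)
  idx <- seq_len(n)
  if (shuffle) idx <- with_seed(seed, sample.int(n))
  n_dev <- ceiling(development_fraction * n)
  x$split[idx[seq_len(n_dev)]] <- "development"
  x$split[idx[-seq_len(n_dev)]] <- "validation"
  x
}

#' Read a simulation scenario from YAML
#'
#' A scenario file bundles a definition recipe (arguments to
#' [generate_definition()]) or a path to a definition file, plus the
#' [simulation_config()] fields. `pair_correlations` is given as a list of
#' `{item1, item2, rho}` entries and `extra_item_betas` as an item -> value
#' map.
#'
#' @param path YAML scenario path.
#' @param seed optional seed overriding the one in the file.
#' @return list with elements `definition` and `config`.
#' @export
read_scenario <- function(path, seed = NULL) {
  sc <- yaml::read_yaml(path)
  definition <- if (!is.null(sc$definition_file)) {
    read_definition(file.path(dirname(path), sc$definition_file))
  } else {
    do.call(generate_definition, sc$definition)
  }
  cfg <- sc$config
  if (!is.null(cfg$extra_item_betas)) {
    cfg$extra_item_betas <- unlist(cfg$extra_item_betas)
  }
  if (!is.null(cfg$pair_correlations)) {
    cfg$pair_correlations <- do.call(rbind, lapply(cfg$pair_correlations, as.data.frame))
  }
  if (!is.null(cfg$prevalences)) cfg$prevalences <- as.numeric(unlist(cfg$prevalences))
  if (!is.null(seed)) cfg$seed <- seed
  config <- do.call(simulation_config, cfg)
  list(definition = definition, config = config, name = sc$name)
}

#' The bundled multicentre-antenatal-cohort scenario
#'
#' Returns the scenario shipped at `inst/extdata/hp4all_like.yaml`: 1752
#' pregnancies screened with the default 50-predictor scorecard, a 16%
#' composite outcome rate driven by 0.06 log-odds per score point, seven
#' items with extra predictive signal of which two carry a negative direct
#' effect masked by correlation with a stronger item, heterogeneous item
#' prevalences (several below 2%), exchangeable latent correlation, and 7%
#' of participants with at least one missing predictor.
#'
#' @param seed optional seed override.
#' @return list with `definition` and `config`.
#' @export
hp4all_scenario <- function(seed = NULL) {
  read_scenario(system.file("extdata", "hp4all_like.yaml",
                            package = "scoreupdate", mustWork = TRUE),
                seed = seed)
}

#' A compact scenario forcing counterintuitive coefficient signs
#'
#' Ten equally weighted predictors, of which three are second-trimester
#' (hence never re-estimated). All seven first-trimester predictors carry
#' extra signal: five with a positive direct effect, two with a negative
#' direct effect but a strong positive latent correlation (0.85) with one of
#' the positive items — so their association on top of the score is positive
#' while their multivariable coefficient is negative. Running the updating
#' procedure on a cohort from this scenario exercises the sign-evaluation
#' step: the two masked items are dropped and the remaining five receive
#' positive additional points.
#'
#' @param seed integer seed for the cohort draw.
#' @param n cohort size (default 5000; large enough that the planted signs
#'   are recovered reliably).
#' @return list with `definition` and `config`.
#' @export
counterintuitive_scenario <- function(seed = 1L, n = 5000L) {
  definition <- scorecard_definition(
    data.frame(
      item_id = sprintf("pred_%02d", 1:10),
      label = sprintf("synthetic predictor item %d", 1:10),
      role = "predictor",
      trimester = rep(c("first", "second"), c(7L, 3L)),
      parity_scope = "all",
      # the seven re-estimated items carry minimal score weight, so their
      # planted effects are genuinely additional to the cumulative score
      points = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 3L, 3L, 3L),
      stringsAsFactors = FALSE
    ),
    cutoff = 6L, version = "counterintuitive-demo"
  )
  strong <- paste0("pred_0", 1:5)
  flips <- c("pred_06", "pred_07")
  extra <- c(rep(1.3, 2), rep(0.9, 3), rep(-0.4, 2))
  names(extra) <- c(strong[1:2], strong[3:5], flips)
  config <- simulation_config(
    n_participants = n,
    prevalences = 0.2,
    correlation = 0.05,
    pair_correlations = data.frame(
      item1 = strong[1:2], item2 = flips, rho = 0.9,
      stringsAsFactors = FALSE
    ),
    target_outcome_rate = 0.16,
    beta_per_point = 0.15,
    extra_item_betas = extra,
    development_fraction = 2 / 3,
    seed = seed
  )
  list(definition = definition, config = config, name = "counterintuitive")
}
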