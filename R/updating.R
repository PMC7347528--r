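# Logistic fit on a design matrix (intercept added), returning coefficients,
# their covariance, and the likelihood-ratio chi-square vs intercept-only.
fit_logit_matrix <- function(x, y) {
  a <- cbind(`(Intercept)` = 1, x)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(a, y, family = stats::binomial())),
    error = function(e) NULL
  )
  if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
  rmat <- qr.R(fit$qr)
  v <- tryCatch(chol2inv(rmat), error = function(e) NULL)
  if (is.null(v)) return(NULL)
  piv <- fit$qr$pivot
  v[piv, piv] <- v
  dimnames(v) <- list(colnames(a), colnames(a))
  separated <- any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10)
  list(coef = fit$coefficients, vcov = v, converged = fit$converged,
       separated = separated, chi2 = fit$null.deviance - fit$deviance,
       df_resid = fit$df.residual)
}

# Item design column for the joint model: multiparous-only items are coded 0
# for nulliparous women (their prior-pregnancy characteristics do not apply).
item_design_column <- function(completion, definition, item) {
  v <- as.numeric(completion[[item]])
  scope <- definition$parity_scope[match(item, definition$item_id)]
  if (identical(scope, "multiparous_only")) {
    v[completion$parity == "nulliparous"] <- 0
  }
  v
}

#' Screen predictors for additional value on top of the cumulative score
#'
#' First updating step. The reference model regresses the outcome on the
#' cumulative score. For each eligible predictor a bivariate model adds that
#' single item; its coefficient is the item's additional effect beyond the
#' score. Fits are run per imputation completion and pooled with Rubin's
#' rules; an item is a candidate when its pooled Wald p-value is below
#' `p_enter`. Second-trimester items are never re-estimated (ineligible);
#' multiparous-only items are evaluated in multiparous women only.
#'
#' @param stack an `imputed_stack` (or complete `cohort`, wrapped as m = 1).
#' @param definition a `scorecard_definition`.
#' @param p_enter candidate threshold on the pooled Wald p (default 0.20).
#' @return object of class `candidate_screen`: data.frame with one row per
#'   predictor item — `item_id`, `eligible`, `estimable`, `beta`, `se`,
#'   `wald_p`, `is_candidate`, `subset` — plus attributes
#'   `reference_beta_per_point` (pooled univariate score coefficient) and
#'   `n_eligible`.
#' @export
screen_candidates <- function(stack, definition, p_enter = 0.20) {
  stack <- as_imputed_stack(stack)
  completions <- stack$completions
  preds <- intersect(predictor_items(definition), item_columns(completions[[1]]))
  meta <- definition[match(preds, definition$item_id), ]
  eligible <- meta$trimester == "first"
  scores <- lapply(completions, compute_cumulative_score, definition = definition)
  ref <- pool_model_term(completions, scores, definition, items = character(0),
                         term = "score")
  rows <- lapply(seq_along(preds), function(i) {
    j <- preds[i]
    base <- data.frame(item_id = j, eligible = eligible[i], estimable = NA,
                       beta = NA_real_, se = NA_real_, wald_p = NA_real_,
                       is_candidate = FALSE,
                       subset = if (meta$parity_scope[i] == "multiparous_only")
                         "multiparous" else "all",
                       stringsAsFactors = FALSE)
    if (!eligible[i]) return(base)
    keep_rows <- if (meta$parity_scope[i] == "multiparous_only") {
      completions[[1]]$parity == "multiparous"
    } else rep(TRUE, nrow(completions[[1]]))
    est <- vapply(seq_along(completions), function(k) {
      comp <- completions[[k]]
      x <- cbind(score = scores[[k]][keep_rows],
                 item = as.numeric(comp[[j]][keep_rows]))
      f <- fit_logit_matrix(x, comp$outcome[keep_rows])
      if (is.null(f) || f$separated || !f$converged) return(c(NA_real_, NA_real_))
      c(f$coef[["item"]], f$vcov["item", "item"])
    }, numeric(2))
    if (anyNA(est)) {
      base$estimable <- FALSE
      return(base)
    }
    pooled <- pool_estimates(est[1, ], est[2, ], df_com = sum(keep_rows) - 3L)
    base$estimable <- TRUE
    base$beta <- pooled$estimate
    base$se <- sqrt(pooled$total_var)
    base$wald_p <- pooled$wald_p
    base$is_candidate <- pooled$wald_p < p_enter
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(!out$estimable, na.rm = TRUE)) {
    warning("non-estimable (separated) item(s) flagged, not candidates: ",
            paste(out$item_id[!out$estimable & !is.na(out$estimable)], collapse = ", "))
  }
  structure(out, class = c("candidate_screen", "data.frame"),
            reference_beta_per_point = ref$pooled[["score"]]$estimate,
            reference_model = ref, n_eligible = sum(eligible))
}

# Fit outcome ~ score + items on every completion and Rubin-pool each term.
pool_model_term <- function(completions, scores, definition, items, term = NULL) {
  n <- nrow(completions[[1]])
  terms <- c("score", items)
  per <- lapply(seq_along(completions), function(k) {
    comp <- completions[[k]]
    x <- cbind(score = as.numeric(scores[[k]]))
    for (j in items) x <- cbind(x, item_design_column(comp, definition, j))
    colnames(x) <- terms
    fit_logit_matrix(x, comp$outcome)
  })
  if (any(vapply(per, is.null, logical(1)))) return(NULL)
  df_com <- per[[1]]$df_resid
  pooled <- lapply(terms, function(tm) {
    est <- vapply(per, function(f) f$coef[[tm]], numeric(1))
    va <- vapply(per, function(f) f$vcov[tm, tm], numeric(1))
    pool_estimates(est, va, df_com = df_com)
  })
  names(pooled) <- terms
  list(pooled = pooled,
       model_chi2 = mean(vapply(per, function(f) f$chi2, numeric(1))),
       converged = all(vapply(per, function(f) f$converged && !f$separated,
                              logical(1))),
       per_completion = per)
}

#' Backward elimination of candidate predictors
#'
#' Second half of the selection: starting from the joint model
#' `outcome ~ score + all candidates`, repeatedly drop the candidate with the
#' largest pooled Wald p-value while it exceeds `p_remove`, refitting after
#' each drop. Multiparous-only items enter the joint model with nulliparous
#' responses coded 0. The model chi-square of the final model (likelihood
#' ratio vs intercept-only, averaged over completions) feeds the shrinkage
#' factor.
#'
#' @param stack an `imputed_stack` or complete `cohort`.
#' @param definition a `scorecard_definition`.
#' @param candidates character vector of candidate item ids (empty is
#'   allowed: the score-only model is returned, with a message).
#' @param p_remove retention threshold (default 0.20).
#' @return list with `selected_items`, `raw_betas` (named, pooled),
#'   `se` (named), `wald_p` (named), `beta_score` (pooled score coefficient
#'   in the final model), `model_chi2`, `elimination_trace` (data.frame of
#'   dropped items with the p-value at removal).
#' @export
backward_eliminate <- function(stack, definition, candidates, p_remove = 0.20) {
  stack <- as_imputed_stack(stack)
  completions <- stack$completions
  scores <- lapply(completions, compute_cumulative_score, definition = definition)
  if (length(candidates) == 0L) message("no candidates: returning score-only model")
  current <- candidates
  trace <- data.frame(item_id = character(0), wald_p = numeric(0),
                      reason = character(0), stringsAsFactors = FALSE)
  repeat {
    fit <- pool_model_term(completions, scores, definition, current)
    if (is.null(fit) || !fit$converged) {
      # degenerate joint fit: drop the most extreme candidate coefficient
      if (length(current) == 0L) stop("score-only model failed to converge")
      betas <- if (is.null(fit)) NULL else
        vapply(current, function(j) fit$pooled[[j]]$estimate, numeric(1))
      victim <- if (is.null(betas)) current[length(current)] else
        current[which.max(abs(betas))]
      warning("joint model degenerate; dropping '", victim, "'")
      trace <- rbind(trace, data.frame(item_id = victim, wald_p = NA_real_,
                                       reason = "non-convergence"))
      current <- setdiff(current, victim)
      next
    }
    if (length(current) == 0L) break
    pvals <- vapply(current, function(j) fit$pooled[[j]]$wald_p, numeric(1))
    if (max(pvals) <= p_remove) break
    victim <- current[which.max(pvals)]
    trace <- rbind(trace, data.frame(item_id = victim, wald_p = max(pvals),
                                     reason = "p above threshold"))
    current <- setdiff(current, victim)
  }
  raw <- vapply(current, function(j) fit$pooled[[j]]$estimate, numeric(1))
  se <- vapply(current, function(j) sqrt(fit$pooled[[j]]$total_var), numeric(1))
  pv <- vapply(current, function(j) fit$pooled[[j]]$wald_p, numeric(1))
  list(selected_items = current, raw_betas = raw, se = se, wald_p = pv,
       beta_score = fit$pooled[["score"]]$estimate,
       se_score = sqrt(fit$pooled[["score"]]$total_var),
       model_chi2 = fit$model_chi2, elimination_trace = trace)
}

#' Heuristic shrinkage factor
#'
#' `(model_chi2 - (df_considered - 1)) / model_chi2`: a multiplicative
#' deflation of the selected coefficients that charges the model for every
#' degree of freedom examined during selection, countering the optimism of
#' data-driven predictor choice. The factor can be zero or negative when the
#' model chi-square is small relative to the degrees of freedom spent — in
#' that case the model carries no transportable signal and all additional
#' points collapse to zero downstream.
#'
#' @param model_chi2 likelihood-ratio chi-square of the final model
#'   (must be positive).
#' @param df_considered total degrees of freedom considered: all predictors
#'   screened during selection plus all covariates fitted in the final model.
#' @return scalar shrinkage factor, at most 1.
#' @export
heuristic_shrinkage <- function(model_chi2, df_considered) {
  if (model_chi2 <= 0) stop("model_chi2 must be positive")
  (model_chi2 - (df_considered - 1)) / model_chi2
}

#' Evaluate coefficient signs of the updated model
#'
#' Every item entered the original scorecard for a positive association with
#' the adverse outcome, so a negative multivariable coefficient is
#' counterintuitive — usually an artefact of correlation between predictors
#' — and the item is dropped. Items negative in both the univariate
#' (score-adjusted single-item) and multivariable analyses are additionally
#' flagged `review_required`: in a clinical revision such items are referred
#' to literature and expert review rather than dropped silently.
#'
#' @param raw_betas named numeric vector of multivariable coefficients.
#' @param univariate_betas named numeric vector of the screening
#'   coefficients for (at least) the same items.
#' @return list with `kept_items`, `dropped_counterintuitive`,
#'   `review_required`.
#' @export
sign_check <- function(raw_betas, univariate_betas) {
  items <- names(raw_betas)
  dropped <- items[raw_betas < 0]
  review <- dropped[!is.na(univariate_betas[dropped]) & univariate_betas[dropped] < 0]
  list(kept_items = setdiff(items, dropped),
       dropped_counterintuitive = dropped,
       review_required = review)
}

#' Rescale shrunken coefficients into additional score points
#'
#' Final updating step: each retained coefficient, after shrinkage, is
#' divided by the coefficient corresponding to one point of cumulative
#' score, so the item's extra effect is expressed in the scorecard's own
#' currency, then rounded to an integer and floored at zero.
#'
#' @param raw_betas named numeric vector of retained multivariable
#'   coefficients.
#' @param shrinkage scalar shrinkage factor; non-positive values collapse
#'   all points to zero, with a warning.
#' @param beta_per_point_reference positive log-odds per score point used as
#'   the denominator.
#' @param rounding `"nearest"` (half rounds up) or `"floor"`.
#' @return named integer vector of non-negative additional points.
#' @export
rescale_to_points <- function(raw_betas, shrinkage, beta_per_point_reference,
                              rounding = c("nearest", "floor")) {
  rounding <- match.arg(rounding)
  if (beta_per_point_reference <= 0) {
    stop("beta_per_point_reference must be positive: the cumulative score carries no information, updating aborts")
  }
  if (length(raw_betas) == 0L) return(stats::setNames(integer(0), character(0)))
  if (shrinkage <= 0) {
    warning("non-positive shrinkage factor: all additional points set to 0")
    return(stats::setNames(integer(length(raw_betas)), names(raw_betas)))
  }
  ratio <- shrinkage * raw_betas / beta_per_point_reference
  pts <- if (rounding == "nearest") floor(ratio + 0.5) else floor(ratio)
  stats::setNames(as.integer(pmax(pts, 0)), names(raw_betas))
}

#' Construct an updated scorecard
#'
#' @param base the original `scorecard_definition`.
#' @param additional_points named integer vector (item id -> extra points)
#'   added on top of the item's original weight.
#' @param cutoff high-risk threshold of the updated instrument (defaults to
#'   the base cutoff).
#' @param mode `"additional"` (default: extra points add to the original
#'   weight) or `"replace"` (extra points replace the item's weight).
#' @return object of class `updated_scorecard`.
#' @export
updated_scorecard <- function(base, additional_points,
                              cutoff = definition_cutoff(base),
                              mode = c("additional", "replace")) {
  mode <- match.arg(mode)
  additional_points <- additional_points[additional_points != 0L]
  bad <- setdiff(names(additional_points), predictor_items(base))
  if (length(bad) > 0L) {
    stop("additional points for unknown predictor item(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(base = base,
                 additional_points = additional_points,
                 cutoff = as.integer(cutoff), mode = mode),
            class = "updated_scorecard")
}

#' @export
print.updated_scorecard <- function(x, ...) {
  cat(sprintf("<updated_scorecard> base '%s', cutoff >= %d, mode %s\n",
              attr(x$base, "version"), x$cutoff, x$mode))
  if (length(x$additional_points) == 0L) {
    cat("  no additional points: identical to the base scorecard\n")
  } else {
    for (j in names(x$additional_points)) {
      cat(sprintf("  %s: +%d point(s)\n", j, x$additional_points[[j]]))
    }
  }
  invisible(x)
}

#' Compute updated cumulative scores
#'
#' The updated score of a participant is her base cumulative score plus the
#' additional points of every updated item she answered positively (in
#' `"replace"` mode the item's original weight is substituted instead of
#' added to). Additional points are non-negative, so the updated score never
#' falls below the base score in `"additional"` mode.
#'
#' @param cohort a `cohort`.
#' @param updated an `updated_scorecard`.
#' @param missing_policy see [compute_cumulative_score()].
#' @return integer score vector.
#' @export
compute_updated_score <- function(cohort, updated,
                                  missing_policy = c("zero", "require_complete")) {
  missing_policy <- match.arg(missing_policy)
  base_score <- compute_cumulative_score(cohort, updated$base, missing_policy)
  add <- updated$additional_points
  if (length(add) == 0L) return(base_score)
  x <- response_matrix(cohort, names(add))
  incomplete <- rowSums(is.na(x)) > 0L
  x[is.na(x)] <- 0L
  extra <- as.integer(x %*% add)
  if (updated$mode == "replace") {
    w <- updated$base$points[match(names(add), updated$base$item_id)]
    extra <- extra - as.integer(x %*% w)
  }
  score <- base_score + extra
  if (missing_policy == "require_complete") score[incomplete] <- NA_integer_
  score
}

#' Run the four-step model-updating procedure
#'
#' Orchestrates, on development data: (1) candidate screening of every
#' eligible predictor on top of the cumulative score, then backward
#' elimination to the final multivariable model; (2) heuristic shrinkage of
#' its coefficients, charging one degree of freedom for every predictor
#' examined plus every covariate fitted; (3) evaluation of coefficient
#' signs, dropping counterintuitive (negative) items; (4) rescaling of the
#' shrunken coefficients into integer additional points via the
#' per-score-point coefficient. Every intermediate table is retained.
#'
#' @param development an `imputed_stack` of the development split, or a
#'   complete development `cohort`.
#' @param definition the original `scorecard_definition`.
#' @param p_enter screening threshold (default 0.20).
#' @param p_remove elimination threshold (default 0.20).
#' @param rounding `"nearest"` or `"floor"` (see [rescale_to_points()]).
#' @param reference `"full_model"` (default: the score coefficient of the
#'   final multivariable model is the rescaling denominator) or
#'   `"reference_model"` (the univariate score coefficient).
#' @param mode passed to [updated_scorecard()].
#' @return list with `model` (class `update_model`: screening table,
#'   selection, shrinkage, sign evaluation, points, provenance) and
#'   `scorecard` (an `updated_scorecard`).
#' @export
run_update <- function(development, definition, p_enter = 0.20,
                       p_remove = 0.20, rounding = "nearest",
                       reference = c("full_model", "reference_model"),
                       mode = "additional") {
  reference <- match.arg(reference)
  stack <- as_imputed_stack(development)
  if (anyNA(response_matrix(stack$completions[[1]],
                            intersect(predictor_items(definition),
                                      item_columns(stack$completions[[1]]))))) {
    stop("development data still has missing predictor entries; impute first")
  }
  check_two_classes(stack$completions[[1]]$outcome)
  screen <- screen_candidates(stack, definition, p_enter = p_enter)
  candidates <- screen$item_id[screen$is_candidate]
  sel <- backward_eliminate(stack, definition, candidates, p_remove = p_remove)
  df_considered <- attr(screen, "n_eligible") + 1L + length(sel$selected_items)
  shrink <- heuristic_shrinkage(sel$model_chi2, df_considered)
  uni <- stats::setNames(screen$beta, screen$item_id)
  signs <- sign_check(sel$raw_betas, uni[sel$selected_items])
  beta_ref <- if (reference == "full_model") sel$beta_score else
    attr(screen, "reference_beta_per_point")
  points <- rescale_to_points(sel$raw_betas[signs$kept_items], shrink,
                              beta_ref, rounding = rounding)
  scorecard <- updated_scorecard(definition, points, mode = mode)
  if (length(points[points > 0L]) == 0L) {
    message("no item earns additional points: updated scorecard equals the base")
  }
  model <- structure(list(
    screen = screen,
    candidates = candidates,
    selected_items = sel$selected_items,
    raw_betas = sel$raw_betas,
    se = sel$se,
    wald_p = sel$wald_p,
    beta_score = sel$beta_score,
    model_chi2 = sel$model_chi2,
    df_considered = df_considered,
    shrinkage = shrink,
    dropped_counterintuitive = signs$dropped_counterintuitive,
    review_required = signs$review_required,
    additional_points = points,
    beta_per_point_reference = beta_ref,
    reference_beta_per_point = attr(screen, "reference_beta_per_point"),
    elimination_trace = sel$elimination_trace,
    settings = list(p_enter = p_enter, p_remove = p_remove,
                    rounding = rounding, reference = reference, mode = mode,
                    m = stack$m)
  ), class = "update_model")
  list(model = model, scorecard = scorecard)
}

#' @export
print.update_model <- function(x, ...) {
  cat(sprintf("<update_model> %d eligible predictors screened, %d candidates, %d selected\n",
              attr(x$screen, "n_eligible"), length(x$candidates),
              length(x$selected_items)))
  cat(sprintf("  model chi2 %.2f on %d considered df -> shrinkage %.3f\n",
              x$model_chi2, x$df_considered, x$shrinkage))
  if (length(x$dropped_counterintuitive) > 0L) {
    cat("  dropped (counterintuitive sign):",
        paste(x$dropped_counterintuitive, collapse = ", "), "\n")
  }
  cat(sprintf("  reference beta per point %.4f; %d item(s) with positive additional points\n",
              x$beta_per_point_reference, sum(x$additional_points > 0L)))
  invisible(x)
}
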