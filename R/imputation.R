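#' Screen predictor items for low incidence
#'
#' Items observed positive in fewer than `threshold` of all participants are
#' excluded from the chained-equations imputation model: rare items make the
#' per-item logistic fits unstable. The denominator is the full sample size
#' (missing responses count in the denominator, not the numerator), so an
#' item with 19 positives among 1000 participants (1.9%) is excluded while
#' one with 20 (2.0%) is kept — the rule is strictly "below" the threshold.
#'
#' @param x a `cohort`.
#' @param definition optional definition; defaults to all item columns,
#'   otherwise restricts to its predictor items.
#' @param threshold incidence proportion (default 0.02).
#' @return list with character vectors `included` and `excluded`.
#' @export
screen_low_incidence <- function(x, definition = NULL, threshold = 0.02) {
  items <- if (is.null(definition)) item_columns(x) else
    intersect(predictor_items(definition), item_columns(x))
  m <- response_matrix(x, items)
  incidence <- colSums(m == 1L, na.rm = TRUE) / nrow(m)
  excluded <- items[incidence < threshold]
  list(included = setdiff(items, excluded), excluded = excluded)
}

#' Multiple imputation by chained equations for binary scorecard items
#'
#' Produces `m` completed copies of the cohort. Each chain initializes the
#' missing predictor entries with draws from the observed values of the same
#' item and then cycles `n_iterations` times over the incomplete items: item
#' j is regressed (logistic) on the other included items and the outcome
#' over its observed rows, a coefficient vector is drawn from the asymptotic
#' normal posterior of the fit, and the missing entries of j are redrawn as
#' Bernoulli with the implied probabilities. Low-incidence items (see
#' [screen_low_incidence()]) are excluded from the model-based step: they are
#' completed by marginal Bernoulli draws at their observed prevalence and
#' never appear as covariates. Items whose fit fails (e.g. one observed
#' category only, or separation) fall back to the same marginal draw, with a
#' warning, and are reported in the `fallback_items` field.
#'
#' Observed entries are never altered; the outcome is always complete by
#' construction of the cohort class.
#'
#' @param x a `cohort`.
#' @param definition a `scorecard_definition` (identifies predictor items).
#' @param m number of completed datasets (default 20).
#' @param n_iterations chained-equation sweeps per chain (default 10).
#' @param seed integer seed; same seed gives bit-identical stacks.
#' @param low_incidence_threshold passed to [screen_low_incidence()].
#' @return an object of class `imputed_stack`: list with `completions` (m
#'   cohorts), `m`, `excluded_items`, `fallback_items`, `seed`.
#' @export
mice_impute <- function(x, definition, m = 20L, n_iterations = 10L, seed = 1L,
                        low_incidence_threshold = 0.02) {
  stopifnot(m >= 1L, n_iterations >= 1L)
  screen <- screen_low_incidence(x, definition, low_incidence_threshold)
  items <- c(screen$included, screen$excluded)
  resp <- response_matrix(x, items)
  miss <- is.na(resp)
  incomplete <- colnames(resp)[colSums(miss) > 0L]
  if (length(incomplete) == 0L) {
    completions <- replicate(m, x, simplify = FALSE)
    return(structure(list(completions = completions, m = as.integer(m),
                          excluded_items = screen$excluded,
                          fallback_items = character(0), seed = as.integer(seed)),
                     class = "imputed_stack"))
  }
  prev_obs <- vapply(colnames(resp),
                     function(j) mean(resp[!miss[, j], j]), numeric(1))
  fallback <- character(0)
  completions <- with_seed(seed, lapply(seq_len(m), function(chain) {
    cur <- resp
    for (j in incomplete) {
      obs <- cur[!miss[, j], j]
      cur[miss[, j], j] <- sample(obs, sum(miss[, j]), replace = TRUE)
    }
    model_items <- intersect(incomplete, screen$included)
    marg_items <- setdiff(incomplete, model_items)
    warm <- list()
    for (it in seq_len(n_iterations)) {
      for (j in model_items) {
        covars <- setdiff(screen$included, j)
        a <- cbind(1, cur[, covars, drop = FALSE], outcome = x$outcome)
        rows <- !miss[, j]
        draw <- impute_draw_logistic(a[rows, , drop = FALSE], cur[rows, j],
                                     a[!rows, , drop = FALSE],
                                     start = warm[[j]])
        warm[[j]] <- attr(draw, "coef")
        if (is.null(draw)) {
          fallback <<- union(fallback, j)
          cur[miss[, j], j] <- stats::rbinom(sum(miss[, j]), 1L, prev_obs[j])
        } else {
          cur[miss[, j], j] <- draw
        }
      }
      for (j in marg_items) {
        cur[miss[, j], j] <- stats::rbinom(sum(miss[, j]), 1L, prev_obs[j])
      }
    }
    done <- x
    for (j in colnames(cur)) done[[j]] <- as.integer(cur[, j])
    done
  }))
  if (length(fallback) > 0L) {
    warning("marginal-draw fallback used for item(s): ",
            paste(sort(fallback), collapse = ", "))
  }
  structure(list(completions = completions, m = as.integer(m),
                 excluded_items = screen$excluded,
                 fallback_items = sort(fallback), seed = as.integer(seed)),
            class = "imputed_stack")
}

# Fit y ~ a (logistic), draw coefficients from the asymptotic posterior, and
# return Bernoulli draws for the rows of a_mis; NULL when the fit degenerates.
# `start` warm-starts the IRLS from the previous sweep's coefficients.
impute_draw_logistic <- function(a_obs, y_obs, a_mis, start = NULL) {
  if (length(unique(y_obs)) < 2L) return(NULL)
  if (!is.null(start) && (length(start) != ncol(a_obs) || anyNA(start))) start <- NULL
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(a_obs, y_obs, family = stats::binomial(),
                                    start = start)),
    error = function(e) if (is.null(start)) NULL else tryCatch(
      suppressWarnings(stats::glm.fit(a_obs, y_obs, family = stats::binomial())),
      error = function(e2) NULL
    )
  )
  if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) return(NULL)
  rmat <- qr.R(fit$qr)
  v <- tryCatch(chol2inv(rmat), error = function(e) NULL)
  if (is.null(v)) return(NULL)
  # undo the QR pivoting so the covariance lines up with the coefficients
  piv <- fit$qr$pivot
  v[piv, piv] <- v
  ch <- tryCatch(chol(v + diag(1e-10, nrow(v))), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- fit$coefficients + drop(t(ch) %*% stats::rnorm(length(fit$coefficients)))
  p <- stats::plogis(drop(a_mis %*% beta))
  structure(stats::rbinom(nrow(a_mis), 1L, p), coef = fit$coefficients)
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("<imputed_stack> m = %d completions of %d participants; %d item(s) excluded (low incidence)\n",
              x$m, nrow(x$completions[[1]]), length(x$excluded_items)))
  if (length(x$fallback_items) > 0L) {
    cat("  marginal fallback for:", paste(x$fallback_items, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Wrap a complete cohort as a single-completion stack
#' @param x a `cohort` without missing predictor entries.
#' @return an `imputed_stack` with `m = 1`.
#' @export
as_imputed_stack <- function(x) {
  if (inherits(x, "imputed_stack")) return(x)
  structure(list(completions = list(x), m = 1L, excluded_items = character(0),
                 fallback_items = character(0), seed = NA_integer_),
            class = "imputed_stack")
}

#' Pool estimates across imputations with Rubin's rules
#'
#' The pooled point estimate is the mean of the per-completion estimates; the
#' total variance is `W + (1 + 1/m) B` with `W` the mean within-imputation
#' variance and `B` the between-imputation variance. The Wald p-value refers
#' `estimate / sqrt(total_var)` to a t distribution with Rubin degrees of
#' freedom, small-sample adjusted (Barnard--Rubin) when the complete-data
#' degrees of freedom `df_com` are supplied. With `m = 1` the single estimate
#' is returned (between-variance 0, normal reference).
#'
#' @param estimates numeric vector of per-completion coefficients.
#' @param variances numeric vector of per-completion squared standard errors.
#' @param df_com complete-data residual degrees of freedom (default `Inf`).
#' @return list of class `pooled_estimate`: `estimate`, `within_var`,
#'   `between_var`, `total_var`, `df`, `statistic`, `wald_p`, `m`.
#' @export
pool_estimates <- function(estimates, variances, df_com = Inf) {
  m <- length(estimates)
  stopifnot(m >= 1L, length(variances) == m)
  if (any(variances <= 0)) stop("input error: variances must be positive")
  est <- mean(estimates)
  w <- mean(variances)
  b <- if (m == 1L) 0 else stats::var(estimates)
  total <- w + (1 + 1 / m) * b
  if (m == 1L || b == 0) {
    df <- Inf
  } else {
    r <- (1 + 1 / m) * b / w
    df_old <- (m - 1) * (1 + 1 / r)^2
    if (is.finite(df_com)) {
      lambda <- (1 + 1 / m) * b / total
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      df <- df_old * df_obs / (df_old + df_obs)
    } else {
      df <- df_old
    }
  }
  stat <- est / sqrt(total)
  p <- if (is.finite(df)) 2 * stats::pt(-abs(stat), df) else 2 * stats::pnorm(-abs(stat))
  structure(list(estimate = est, within_var = w, between_var = b,
                 total_var = total, df = df, statistic = stat, wald_p = p,
                 m = m), class = "pooled_estimate")
}

#' Write an imputed stack to disk
#'
#' One CSV per completion plus a JSON manifest (`m`, `seed`,
#' `excluded_items`, `fallback_items`, file names).
#'
#' @param stack an `imputed_stack`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_imputed_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("completion_%02d.csv", seq_len(stack$m))
  for (i in seq_len(stack$m)) {
    write_cohort(stack$completions[[i]], file.path(dir, files[i]))
  }
  jsonlite::write_json(
    list(m = stack$m, seed = stack$seed, excluded_items = stack$excluded_items,
         fallback_items = stack$fallback_items, files = files),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Read an imputed stack written by [write_imputed_stack()]
#' @param dir directory holding the manifest and completion CSVs.
#' @return an `imputed_stack`.
#' @export
read_imputed_stack <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  completions <- lapply(man$files, function(f) read_cohort(file.path(dir, f)))
  structure(list(completions = completions, m = as.integer(man$m),
                 excluded_items = as.character(man$excluded_items %||% character(0)),
                 fallback_items = as.character(man$fallback_items %||% character(0)),
                 seed = as.integer(man$seed)),
            class = "imputed_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
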