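# Small fixtures and independent oracles used across the suite.

# A compact definition: n predictors with given weights, optional awareness.
tiny_definition <- function(weights = c(1L, 2L, 3L, 1L, 2L), n_awareness = 0L,
                            cutoff = 3L, trimester = NULL, parity_scope = NULL) {
  k <- length(weights)
  items <- data.frame(
    item_id = sprintf("pred_%02d", seq_len(k)),
    label = sprintf("item %d", seq_len(k)),
    role = "predictor",
    trimester = if (is.null(trimester)) "first" else trimester,
    parity_scope = if (is.null(parity_scope)) "all" else parity_scope,
    points = as.integer(weights),
    stringsAsFactors = FALSE
  )
  if (n_awareness > 0L) {
    items <- rbind(items, data.frame(
      item_id = sprintf("aware_%02d", seq_len(n_awareness)),
      label = "aware", role = "awareness", trimester = "first",
      parity_scope = "all", points = 0L, stringsAsFactors = FALSE
    ))
  }
  scorecard_definition(items, cutoff = cutoff, version = "tiny")
}

# A cohort from an explicit response matrix.
tiny_cohort <- function(responses, outcome = NULL, parity = "nulliparous") {
  responses <- as.data.frame(responses)
  n <- nrow(responses)
  if (is.null(outcome)) outcome <- rep(c(0L, 1L), length.out = n)
  if (length(parity) == 1L) parity <- rep(parity, n)
  cohort(responses, outcome = outcome, parity = parity)
}

# Plain data.frame view of a cohort, shorn of generator metadata attributes.
plain_df <- function(x) {
  out <- as.data.frame(x)
  attr(out, "true_intercept") <- NULL
  out
}

# Brute-force weighted sum, element by element.
oracle_score <- function(mat, weights) {
  vapply(seq_len(nrow(mat)), function(i) {
    s <- 0L
    for (j in seq_len(ncol(mat))) {
      v <- mat[i, j]
      if (!is.na(v) && v == 1L) s <- s + weights[j]
    }
    s
  }, integer(1))
}

# All-pairs Mann-Whitney AUC.
oracle_auc <- function(scores, outcome) {
  cases <- scores[outcome == 1]
  controls <- scores[outcome == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cases) * length(controls))
}

# Rubin's rules written out directly.
oracle_rubin <- function(est, va) {
  m <- length(est)
  qbar <- sum(est) / m
  w <- sum(va) / m
  b <- sum((est - qbar)^2) / (m - 1)
  t <- w + (1 + 1 / m) * b
  list(estimate = qbar, within = w, between = b, total = t)
}

# Textbook Pearson chi-square statistic.
oracle_chisq_stat <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Independent backward-elimination trace: stats::glm-based, drop the largest
# pooled p above the threshold, on a complete (m = 1) cohort.
oracle_backward <- function(x, definition, candidates, p_remove = 0.20) {
  score <- compute_cumulative_score(x, definition)
  current <- candidates
  repeat {
    dat <- data.frame(outcome = x$outcome, score = score)
    for (j in current) {
      v <- x[[j]]
      scope <- definition$parity_scope[match(j, definition$item_id)]
      if (identical(scope, "multiparous_only")) v[x$parity == "nulliparous"] <- 0L
      dat[[j]] <- v
    }
    fit <- stats::glm(outcome ~ ., data = dat, family = stats::binomial())
    if (length(current) == 0L) return(character(0))
    co <- summary(fit)$coefficients
    # normal reference: with a single dataset the pooled Wald p is normal-based
    z <- co[current, "Estimate"] / co[current, "Std. Error"]
    p <- 2 * stats::pnorm(-abs(z))
    names(p) <- current
    if (max(p) <= p_remove) return(current)
    current <- setdiff(current, names(which.max(p)))
  }
}

# Tetrachoric correlation approximation from the odds ratio (Digby/Edwards).
approx_tetrachoric <- function(x, y) {
  a <- sum(x == 1 & y == 1) + 0.5
  b <- sum(x == 1 & y == 0) + 0.5
  cc <- sum(x == 0 & y == 1) + 0.5
  d <- sum(x == 0 & y == 0) + 0.5
  or34 <- ((a * d) / (b * cc))^(pi / 4)
  (or34 - 1) / (or34 + 1)
}
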