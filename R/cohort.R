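#' Construct a cohort
#'
#' A cohort is the universal currency of the pipeline: one row per pregnancy,
#' with a unique `participant_id`, a complete binary composite `outcome`
#' (preterm birth and/or small-for-gestational-age), `parity`
#' (`"nulliparous"`/`"multiparous"`), a `split` label
#' (`"development"`/`"validation"`/`"unassigned"`), and one 0/1/`NA` column
#' per scorecard item.
#'
#' @param responses data.frame or matrix of item responses (0/1/`NA`),
#'   columns named by item id.
#' @param outcome integer 0/1 vector, no missing values.
#' @param parity character vector, `"nulliparous"` or `"multiparous"`.
#' @param split character vector; defaults to `"unassigned"`.
#' @param participant_id unique keys; defaults to `p0001`, `p0002`, ...
#' @return An object of class `cohort` (a data.frame).
#' @export
cohort <- function(responses, outcome, parity,
                   split = "unassigned", participant_id = NULL) {
  responses <- as.data.frame(responses)
  n <- nrow(responses)
  if (is.null(participant_id)) {
    participant_id <- sprintf("p%0*d", max(4L, nchar(n)), seq_len(n))
  }
  if (length(split) == 1L) split <- rep(split, n)
  df <- data.frame(
    participant_id = as.character(participant_id),
    outcome = as.integer(outcome),
    parity = as.character(parity),
    split = as.character(split),
    stringsAsFactors = FALSE
  )
  for (j in names(responses)) df[[j]] <- as.integer(responses[[j]])
  out <- structure(df, class = c("cohort", "data.frame"))
  validate_cohort(out)
  out
}

#' Validate a cohort
#'
#' Checks unique participant ids, a complete 0/1 outcome, known parity and
#' split labels, and 0/1/`NA` item entries. When a definition is supplied,
#' item columns must all match its item ids.
#'
#' @param x a `cohort`.
#' @param definition optional `scorecard_definition` to check columns against.
#' @return `x`, invisibly, or an error naming the offending rows/columns.
#' @export
validate_cohort <- function(x, definition = NULL) {
  if (anyDuplicated(x$participant_id)) {
    stop("cohort invalid: duplicated participant_id(s): ",
         paste(unique(x$participant_id[duplicated(x$participant_id)]), collapse = ", "))
  }
  if (anyNA(x$outcome)) {
    stop("cohort invalid: outcome missing for participant(s): ",
         paste(x$participant_id[is.na(x$outcome)], collapse = ", "))
  }
  if (!all(x$outcome %in% c(0L, 1L))) stop("cohort invalid: outcome must be 0/1")
  if (!all(x$parity %in% c("nulliparous", "multiparous"))) {
    stop("cohort invalid: parity must be 'nulliparous' or 'multiparous'")
  }
  if (!all(x$split %in% c("development", "validation", "unassigned"))) {
    stop("cohort invalid: split must be development/validation/unassigned")
  }
  for (j in item_columns(x)) {
    v <- x[[j]]
    bad <- !(is.na(v) | v %in% c(0L, 1L))
    if (any(bad)) {
      stop("cohort invalid: non-binary entries in item '", j, "' for participant(s): ",
           paste(x$participant_id[bad], collapse = ", "))
    }
  }
  if (!is.null(definition)) {
    unknown <- setdiff(item_columns(x), definition$item_id)
    if (length(unknown) > 0L) {
      stop("cohort invalid: unknown item column(s): ", paste(unknown, collapse = ", "))
    }
  }
  invisible(x)
}

reserved_cohort_columns <- c("participant_id", "outcome", "parity", "split")

#' Item columns of a cohort
#' @param x a `cohort`.
#' @return character vector of item-response column names.
#' @export
item_columns <- function(x) setdiff(names(x), reserved_cohort_columns)

#' Item-response matrix of a cohort
#' @param x a `cohort`.
#' @param items optional subset of item ids.
#' @return integer matrix (participants x items) with `NA` for missing.
#' @export
response_matrix <- function(x, items = NULL) {
  if (is.null(items)) items <- item_columns(x)
  m <- as.matrix(as.data.frame(x)[, items, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- x$participant_id
  m
}

#' Subset a cohort by split label
#' @param x a `cohort`.
#' @param split `"development"` or `"validation"`.
#' @return a `cohort`.
#' @export
cohort_split <- function(x, split) {
  stopifnot(split %in% c("development", "validation", "unassigned"))
  out <- x[x$split == split, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cohort", "data.frame"))
}

#' Flag participants with complete first-trimester predictor responses
#'
#' The complete-case rule used for domain validation: a participant is
#' complete iff every first-trimester predictor item is observed. Awareness
#' items and second-trimester items do not affect completeness.
#'
#' @param x a `cohort`.
#' @param definition a `scorecard_definition`.
#' @return logical vector.
#' @export
is_complete_case <- function(x, definition) {
  items <- intersect(predictor_items(definition, trimester = "first"), item_columns(x))
  rowSums(is.na(response_matrix(x, items))) == 0L
}

#' Fraction of participants with at least one missing predictor response
#' @param x a `cohort`.
#' @param definition optional definition; defaults to all item columns.
#' @return proportion in [0, 1].
#' @export
participant_missing_rate <- function(x, definition = NULL) {
  items <- if (is.null(definition)) item_columns(x) else
    intersect(predictor_items(definition), item_columns(x))
  mean(rowSums(is.na(response_matrix(x, items))) > 0L)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d participants, %d item columns; outcome rate %.1f%%\n",
    nrow(x), length(item_columns(x)), 100 * mean(x$outcome)
  ))
  tab <- table(factor(x$split, levels = c("development", "validation", "unassigned")))
  cat("  split:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read a cohort from CSV
#'
#' Expects columns `participant_id`, `outcome`, `parity`, `split`, then one
#' column per item; missing responses are empty cells. Validation is strict:
#' malformed entries, duplicate ids, incomplete outcomes, and (given a
#' definition) unknown item columns all raise errors naming the offenders.
#'
#' @param path CSV file path.
#' @param definition optional `scorecard_definition` for column validation.
#' @return a `cohort`.
#' @export
read_cohort <- function(path, definition = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  need <- reserved_cohort_columns
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  items <- setdiff(names(df), need)
  out <- cohort(
    responses = df[, items, drop = FALSE],
    outcome = df$outcome, parity = df$parity, split = df$split,
    participant_id = df$participant_id
  )
  validate_cohort(out, definition)
  out
}

#' Write a cohort to CSV
#' @param x a `cohort`.
#' @param path output path; missing responses become empty cells.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
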