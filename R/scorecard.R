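#' Construct a scorecard definition
#'
#' A scorecard definition is the item inventory of a points-based risk
#' instrument: each item has an identifier, a role (`"predictor"` items carry
#' an integer weight of 0--3 points, `"awareness"` items are unscored flags),
#' a trimester of assessment, and a parity scope (some prior-pregnancy items
#' apply to multiparous women only). The cumulative score of a participant is
#' the weighted sum of her positive predictor responses; scores at or above
#' `cutoff` classify her as high risk.
#'
#' @param items data.frame with columns `item_id`, `label`, `role`,
#'   `trimester`, `parity_scope`, `points`.
#' @param cutoff integer high-risk threshold (default 16).
#' @param version free-text version string.
#' @return An object of class `scorecard_definition`: the item data.frame
#'   with `cutoff` and `version` attributes.
#' @examples
#' def <- generate_definition(10, 4, 20, seed = 1)
#' max_possible_score(def)
#' @export
scorecard_definition <- function(items, cutoff = 16L, version = "unversioned") {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  required <- c("item_id", "label", "role", "trimester", "parity_scope", "points")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0L) {
    stop("definition is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  items <- items[, required]
  items$item_id <- as.character(items$item_id)
  items$label <- as.character(items$label)
  items$role <- as.character(items$role)
  items$trimester <- as.character(items$trimester)
  items$parity_scope <- as.character(items$parity_scope)
  items$points <- as.integer(items$points)
  items$points[items$role == "awareness"] <- 0L
  rownames(items) <- NULL
  def <- structure(items,
    cutoff = as.integer(cutoff),
    version = as.character(version),
    class = c("scorecard_definition", "data.frame")
  )
  validate_definition(def)
  def
}

#' Validate a scorecard definition
#'
#' Checks the structural invariants: unique item ids, known role / trimester /
#' parity values, predictor points in 0--3, and a cutoff within the achievable
#' score range.
#'
#' @param def a `scorecard_definition`.
#' @return `def`, invisibly, or an error describing the violation.
#' @export
validate_definition <- function(def) {
  if (anyDuplicated(def$item_id)) {
    stop("definition invalid: duplicated item_id(s): ",
         paste(unique(def$item_id[duplicated(def$item_id)]), collapse = ", "))
  }
  if (!all(def$role %in% c("predictor", "awareness"))) {
    stop("definition invalid: role must be 'predictor' or 'awareness'")
  }
  if (!all(def$trimester %in% c("first", "second"))) {
    stop("definition invalid: trimester must be 'first' or 'second'")
  }
  if (!all(def$parity_scope %in% c("all", "multiparous_only"))) {
    stop("definition invalid: parity_scope must be 'all' or 'multiparous_only'")
  }
  pred <- def$role == "predictor"
  if (any(is.na(def$points[pred])) || !all(def$points[pred] %in% 0:3)) {
    stop("definition invalid: predictor points must be integers in 0..3")
  }
  if (any(def$points[!pred] != 0L)) {
    stop("definition invalid: awareness items must carry no points")
  }
  cutoff <- attr(def, "cutoff")
  if (is.na(cutoff) || cutoff < 0L || cutoff > max_possible_score(def)) {
    stop("definition invalid: cutoff must lie in [0, max_possible_score]")
  }
  invisible(def)
}

#' @export
print.scorecard_definition <- function(x, ...) {
  pred <- x$role == "predictor"
  cat(sprintf(
    "<scorecard_definition '%s'>\n  %d predictor items (max score %d), %d awareness items\n",
    attr(x, "version"), sum(pred), max_possible_score(x), sum(!pred)
  ))
  cat(sprintf(
    "  %d second-trimester, %d multiparous-only; high-risk cutoff >= %d\n",
    sum(x$trimester == "second"), sum(x$parity_scope == "multiparous_only"),
    attr(x, "cutoff")
  ))
  invisible(x)
}

#' Item ids of predictor items
#'
#' @param def a `scorecard_definition`.
#' @param trimester optionally restrict to `"first"` or `"second"` trimester.
#' @return character vector of item ids.
#' @export
predictor_items <- function(def, trimester = NULL) {
  keep <- def$role == "predictor"
  if (!is.null(trimester)) keep <- keep & def$trimester %in% trimester
  def$item_id[keep]
}

#' Item ids of awareness items
#' @param def a `scorecard_definition`.
#' @return character vector of item ids.
#' @export
awareness_items <- function(def) def$item_id[def$role == "awareness"]

#' High-risk cutoff of a definition
#' @param def a `scorecard_definition`.
#' @return integer cutoff.
#' @export
definition_cutoff <- function(def) attr(def, "cutoff")

#' Maximum achievable cumulative score
#'
#' The sum of the point weights of all predictor items; awareness items never
#' contribute.
#'
#' @param def a `scorecard_definition`.
#' @return integer.
#' @export
max_possible_score <- function(def) {
  as.integer(sum(def$points[def$role == "predictor"]))
}

#' Compute cumulative scorecard scores
#'
#' Sums, per participant, the point weights of the predictor items answered
#' positively. Awareness items are ignored. Missing responses are governed by
#' `missing_policy`: under `"zero"` an unanswered item contributes 0 points
#' (an unticked box on the paper scorecard scores nothing); under
#' `"require_complete"` participants with any missing predictor response get
#' an `NA` score, supporting complete-case analyses.
#'
#' @param cohort a [cohort] object.
#' @param definition a `scorecard_definition`; every predictor column of the
#'   cohort must match one of its item ids, and all first-trimester predictor
#'   items must be present as columns.
#' @param missing_policy `"zero"` (default) or `"require_complete"`.
#' @return integer vector of scores, one per participant (`NA` for flagged
#'   incomplete participants under `"require_complete"`).
#' @export
compute_cumulative_score <- function(cohort, definition,
                                     missing_policy = c("zero", "require_complete")) {
  missing_policy <- match.arg(missing_policy)
  cols <- item_columns(cohort)
  unknown <- setdiff(cols, definition$item_id)
  if (length(unknown) > 0L) {
    stop("definition mismatch: cohort has item columns not in the definition: ",
         paste(unknown, collapse = ", "))
  }
  needed <- predictor_items(definition, trimester = "first")
  absent <- setdiff(needed, cols)
  if (length(absent) > 0L) {
    stop("definition mismatch: cohort lacks first-trimester predictor columns: ",
         paste(absent, collapse = ", "))
  }
  pred_cols <- intersect(cols, predictor_items(definition))
  w <- definition$points[match(pred_cols, definition$item_id)]
  if (any(w < 0L)) stop("definition invalid: negative point weights")
  x <- as.matrix(as.data.frame(cohort)[, pred_cols, drop = FALSE])
  storage.mode(x) <- "integer"
  incomplete <- rowSums(is.na(x)) > 0L
  x[is.na(x)] <- 0L
  score <- as.integer(x %*% w)
  if (missing_policy == "require_complete") score[incomplete] <- NA_integer_
  score
}

#' Classify participants as high risk
#'
#' A participant is high risk when her cumulative score reaches the cutoff
#' (score >= cutoff). The original instrument selects the upper tail of the
#' score distribution this way.
#'
#' @param scores non-negative integer score vector (`NA` allowed, propagated).
#' @param cutoff integer threshold (default 16).
#' @return integer 0/1 vector.
#' @export
classify_high_risk <- function(scores, cutoff = 16L) {
  if (any(scores < 0, na.rm = TRUE)) stop("scores must be non-negative")
  as.integer(scores >= cutoff)
}

#' Read a scorecard definition from YAML or JSON
#'
#' The file holds `version`, `cutoff`, and an `items` list whose entries have
#' keys `item_id`, `label`, `role`, `trimester`, `parity_scope`, `points`
#' (points optional for awareness items). An optional `additional_points`
#' block (item_id -> integer) re-creates an updated scorecard.
#'
#' @param path file path; format chosen by extension (`.json` vs `.yaml`/`.yml`).
#' @return a `scorecard_definition`, or an `updated_scorecard` when the file
#'   has an `additional_points` block.
#' @export
read_definition <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  items <- do.call(rbind, lapply(obj$items, function(it) {
    data.frame(
      item_id = it$item_id,
      label = if (is.null(it$label)) it$item_id else it$label,
      role = it$role,
      trimester = if (is.null(it$trimester)) "first" else it$trimester,
      parity_scope = if (is.null(it$parity_scope)) "all" else it$parity_scope,
      points = if (is.null(it$points)) 0L else as.integer(it$points),
      stringsAsFactors = FALSE
    )
  }))
  def <- scorecard_definition(
    items,
    cutoff = if (is.null(obj$cutoff)) 16L else obj$cutoff,
    version = if (is.null(obj$version)) "unversioned" else obj$version
  )
  if (!is.null(obj$additional_points) && length(obj$additional_points) > 0L) {
    ap <- vapply(obj$additional_points, function(v) as.integer(v), integer(1))
    return(updated_scorecard(def, ap, cutoff = attr(def, "cutoff")))
  }
  def
}

#' Write a scorecard definition to YAML or JSON
#'
#' @param def a `scorecard_definition` or `updated_scorecard`.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_definition <- function(def, path) {
  add <- NULL
  if (inherits(def, "updated_scorecard")) {
    add <- def$additional_points
    base <- def$base
    cutoff <- def$cutoff
  } else {
    base <- def
    cutoff <- attr(def, "cutoff")
  }
  items <- lapply(seq_len(nrow(base)), function(i) {
    it <- as.list(base[i, , drop = FALSE])
    lapply(it, function(v) if (is.integer(v)) as.integer(v) else as.character(v))
  })
  obj <- list(
    version = attr(base, "version"),
    cutoff = as.integer(cutoff),
    items = items
  )
  if (!is.null(add) && length(add) > 0L) obj$additional_points <- as.list(add)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' Default synthetic scorecard definition
#'
#' A stand-in for the real antenatal instrument, whose item wording is not
#' public: 50 predictor items with weights in 1--3 summing to a maximum score
#' of 98, of which 3 are assessed in the second trimester and 5 (prior-
#' pregnancy characteristics) apply to multiparous women only, plus 26
#' unscored awareness items; high-risk cutoff 16. Item labels are
#' placeholders; real deployments load their own definition file.
#'
#' @return a `scorecard_definition`.
#' @export
default_definition <- function() {
  def <- generate_definition(
    n_predictors = 50L, n_awareness = 26L, target_max_score = 98L, seed = 101L,
    n_second_trimester = 3L, n_multiparous_only = 5L
  )
  attr(def, "version") <- "synthetic-default-1"
  def
}
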