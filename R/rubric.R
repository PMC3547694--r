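# The 11-item performance-indicator rubric and the 0/1/2 scoring engine.

#' Built-in performance-indicator rubric
#'
#' The 11 performance indicators for initial regional medical command and
#' control. Each indicator names one decision kind and a stipulated time
#' standard in minutes from alert: 2 points if the decision was documented
#' within the standard, 1 point if documented later, 0 points if never
#' documented.
#'
#' @return A data frame with columns `id` (1--11), `label`, `kind` (one of
#'   [decision_kinds()]), `standard_minutes`.
#' @export
builtin_rubric <- function() {
  data.frame(
    id = 1:11,
    label = c(
      "Declaration of major incident",
      "Decision on level of alert for staff",
      "Decision on sending additional resources to scene",
      "Decision on receiving hospitals",
      "Establishing contact with incident officers at scene",
      "Decision on preliminary referrals",
      "First information to media",
      "Formulate general guidelines for response",
      "Ensuring adequate information for decision on referrals",
      "Assessment if resources in own organization are adequate",
      "Notify decision on referrals to receiving hospitals"
    ),
    kind = decision_kinds(),
    standard_minutes = c(1, 3, 3, 5, 10, 10, 15, 15, 20, 30, 40),
    stringsAsFactors = FALSE
  )
}

#' Read a rubric from a JSON config file
#'
#' Accepts the same schema as [builtin_rubric()] (an array of objects with
#' `id`, `label`, `kind`, `standard_minutes`), allowing modified indicator
#' sets to be swapped in.
#'
#' @param path JSON file path.
#' @return Rubric data frame, validated like the built-in set.
#' @export
read_rubric <- function(path) {
  df <- jsonlite::fromJSON(path)
  validate_rubric(df)
  df[order(df$id), c("id", "label", "kind", "standard_minutes")]
}

validate_rubric <- function(rubric) {
  if (!is.data.frame(rubric) ||
      !all(c("id", "kind", "standard_minutes") %in% names(rubric))) {
    stop("rubric must have columns id, kind, standard_minutes", call. = FALSE)
  }
  if (nrow(rubric) != 11L || !setequal(rubric$id, 1:11)) {
    stop("rubric must contain exactly 11 indicators with ids 1-11",
         call. = FALSE)
  }
  if (!all(rubric$kind %in% decision_kinds()) ||
      anyDuplicated(rubric$kind)) {
    stop("rubric kinds must be a bijection with the 11 decision kinds",
         call. = FALSE)
  }
  if (any(rubric$standard_minutes <= 0)) {
    stop("time standards must be positive", call. = FALSE)
  }
  invisible(rubric)
}

#' Score one indicator for one incident
#'
#' The boundary is inclusive: a decision documented at exactly the standard
#' scores 2 ("within" the stipulated time frame). A decision documented
#' without a usable timestamp is `NA` (unevaluable) by default, which marks
#' the incident's documentation incomplete; with `lenient_timeless = TRUE` it
#' scores 1 instead.
#'
#' @param record An [incident_record()].
#' @param definition One row of a rubric data frame.
#' @param lenient_timeless Score timeless-but-present decisions 1 instead of
#'   marking them unevaluable. Default `FALSE`.
#' @return Integer 0, 1 or 2, or `NA` for unevaluable.
#' @export
score_indicator <- function(record, definition, lenient_timeless = FALSE) {
  el <- elapsed_minutes(record, definition$kind)
  if (identical(el, "absent")) return(0L)
  if (identical(el, "present_without_time")) {
    return(if (lenient_timeless) 1L else NA_integer_)
  }
  if (el <= definition$standard_minutes) 2L else 1L
}

#' Score one incident against the full rubric
#'
#' @param record An [incident_record()].
#' @param rubric Rubric data frame (default [builtin_rubric()]); must contain
#'   exactly 11 indicators with ids 1--11.
#' @param lenient_timeless See [score_indicator()].
#' @return A `score_vector`: list with `incident_id`, `scores` (named integer
#'   vector of length 11 in indicator-id order, `NA` = unevaluable) and
#'   `complete` (no unevaluable entries).
#' @export
score_incident <- function(record, rubric = builtin_rubric(),
                           lenient_timeless = FALSE) {
  validate_rubric(rubric)
  rubric <- rubric[order(rubric$id), ]
  scores <- vapply(seq_len(nrow(rubric)), function(i) {
    score_indicator(record, rubric[i, ], lenient_timeless)
  }, integer(1))
  names(scores) <- paste0("ind_", rubric$id)
  structure(
    list(incident_id = record$incident_id, scores = scores,
         complete = !anyNA(scores)),
    class = "score_vector"
  )
}

#' Per-indicator aggregation of a score matrix
#'
#' Computes the mean score per indicator and the counts of objectives met
#' completely or partly (score 1 or 2) versus not met at all (score 0),
#' overall and per indicator.
#'
#' @param matrix A complete incidents-by-indicators score matrix (integer
#'   values in 0, 1, 2), e.g. from [build_cohort()].
#' @return List with `per_indicator` (data frame: `indicator_id`, `mean`,
#'   `n_met`, `n_not_met`) and `totals` (list: `n_cells`, `n_met`,
#'   `n_not_met`).
#' @export
aggregate_scores <- function(matrix) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0L || ncol(matrix) == 0L) {
    stop("empty score matrix", call. = FALSE)
  }
  if (anyNA(matrix)) {
    stop("score matrix contains unevaluable cells", call. = FALSE)
  }
  per <- data.frame(
    indicator_id = seq_len(ncol(matrix)),
    mean = colMeans(matrix),
    n_met = colSums(matrix > 0),
    n_not_met = colSums(matrix == 0),
    row.names = NULL
  )
  list(
    per_indicator = per,
    totals = list(n_cells = length(matrix),
                  n_met = sum(matrix > 0),
                  n_not_met = sum(matrix == 0))
  )
}
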