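# Case-flow filters (applicability, documentation completeness) and
# descriptive cohort summaries.

#' Applicability of the indicator set to an incident
#'
#' The indicator set applies, as a set, to incidents that directly or
#' indirectly involve casualties: accidents, threats, fires and CBRNE events.
#' Incidents with other characteristics and time frames
#' (hospital-infrastructure interference, infectious events, weather alerts,
#' regional support, incidents abroad) are not assessable with this set. A
#' record may carry an explicit `applicable_override` flag which takes
#' precedence over the category rule.
#'
#' @param record An [incident_record()].
#' @return List with `applicable` (logical) and `reason` (text).
#' @export
classify_applicability <- function(record) {
  stopifnot(inherits(record, "incident_record"))
  if (!is.na(record$applicable_override)) {
    return(list(applicable = record$applicable_override,
                reason = "explicit override flag"))
  }
  applicable_categories <- c("accident", "threat", "fire", "cbrne")
  ok <- record$category %in% applicable_categories
  list(
    applicable = ok,
    reason = if (ok) {
      paste0("category '", record$category, "' involves casualties")
    } else {
      paste0("category '", record$category,
             "' has different characteristics and time frames")
    }
  )
}

#' Build the scoreable cohort and its case flow
#'
#' Applies the applicability filter, scores every applicable incident against
#' the rubric, and drops incidents whose documentation is incomplete (any
#' unevaluable indicator). Flow counts satisfy
#' `n_total = n_not_applicable + n_applicable` and
#' `n_applicable = n_incomplete + n_scoreable`.
#'
#' @param records Non-empty list of [incident_record()] with unique ids.
#' @param rubric Rubric data frame; default [builtin_rubric()].
#' @param lenient_timeless See [score_indicator()].
#' @return List with `flow` (a `cohort_flow` list of the five stage counts),
#'   `matrix` (`n_scoreable` x 11 integer score matrix, rownames incident
#'   ids, one observation per cell), and `decisions` (data frame logging each
#'   incident's filter outcome).
#' @export
build_cohort <- function(records, rubric = builtin_rubric(),
                         lenient_timeless = FALSE) {
  if (length(records) == 0L) stop("empty cohort", call. = FALSE)
  ids <- vapply(records, function(r) r$incident_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate incident_id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  validate_rubric(rubric)

  app <- lapply(records, classify_applicability)
  applicable <- vapply(app, function(a) a$applicable, logical(1))
  reasons <- vapply(app, function(a) a$reason, character(1))

  vectors <- lapply(records[applicable], score_incident, rubric = rubric,
                    lenient_timeless = lenient_timeless)
  complete <- vapply(vectors, function(v) v$complete, logical(1))

  n_total <- length(records)
  n_applicable <- sum(applicable)
  if (n_applicable == 0L) {
    stop("no incidents remain after the applicability filter", call. = FALSE)
  }
  n_scoreable <- sum(complete)
  if (n_scoreable == 0L) {
    stop("no incidents remain after the documentation-completeness filter",
         call. = FALSE)
  }

  mat <- do.call(rbind, lapply(vectors[complete], function(v) v$scores))
  rownames(mat) <- vapply(vectors[complete], function(v) v$incident_id,
                          character(1))

  status <- character(n_total)
  status[!applicable] <- "not_applicable"
  status[applicable] <- ifelse(complete, "scoreable", "incomplete")
  decisions <- data.frame(incident_id = ids, applicable = applicable,
                          status = status, reason = reasons,
                          stringsAsFactors = FALSE)

  flow <- structure(
    list(n_total = n_total, n_not_applicable = n_total - n_applicable,
         n_applicable = n_applicable,
         n_incomplete = n_applicable - n_scoreable,
         n_scoreable = n_scoreable),
    class = "cohort_flow"
  )
  list(flow = flow, matrix = mat, decisions = decisions)
}

#' Descriptive summary of an incident cohort
#'
#' Category and staffing-extent counts over the whole cohort, the median
#' activation duration, the fraction of incidents active for 4 h (240 min,
#' inclusive) or less, and casualty/hospital summaries.
#'
#' @param records Non-empty list of [incident_record()].
#' @return List with `n_total`, `category_counts`, `staffing_counts`,
#'   `duration_median_minutes`, `frac_leq_4h`, `casualty_total`,
#'   `n_multi_hospital`, `n_hospital_plan`.
#' @export
descriptive_summary <- function(records) {
  if (length(records) == 0L) stop("empty cohort", call. = FALSE)
  cats <- vapply(records, function(r) r$category, character(1))
  staff <- vapply(records, function(r) r$staffing_extent, character(1))
  dur <- vapply(records, function(r) r$active_minutes, numeric(1))
  cas <- vapply(records, function(r) r$casualties, integer(1))
  rh <- vapply(records, function(r) r$receiving_hospitals, integer(1))
  plan <- vapply(records, function(r) r$hospital_plan_activated, logical(1))

  count_by <- function(x, levels) {
    out <- vapply(levels, function(l) sum(x == l), integer(1))
    names(out) <- levels
    out
  }
  list(
    n_total = length(records),
    category_counts = count_by(cats, incident_categories()),
    staffing_counts = count_by(staff, staffing_extents()),
    duration_median_minutes = stats::median(dur),
    frac_leq_4h = mean(dur <= 240),
    casualty_total = sum(cas, na.rm = TRUE),
    n_multi_hospital = sum(rh > 1, na.rm = TRUE),
    n_hospital_plan = sum(plan, na.rm = TRUE)
  )
}
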