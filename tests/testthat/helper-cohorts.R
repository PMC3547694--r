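# Shared fixture builders: records constructed in code, no stored data.

event_at <- function(kind, minutes) decision_event(kind, minutes)

# A record with chosen decisions; `times` is a named vector kind -> minutes
# (NA = documented without timestamp).
make_record <- function(id = "MI-1", category = "accident", times = NULL,
                        alert = "2006-01-01T10:00:00Z", ...) {
  events <- if (is.null(times)) list() else
    lapply(seq_along(times), function(i) {
      decision_event(names(times)[i], times[[i]])
    })
  incident_record(incident_id = id, category = category, alert_time = alert,
                  events = events, ...)
}

# Record scoring `value` on every indicator: 2 -> all events at minute 0,
# 1 -> all events just past their standard, 0 -> no events.
uniform_record <- function(id, value, category = "accident",
                           rubric = builtin_rubric(), ...) {
  times <- switch(as.character(value),
    "2" = stats::setNames(rep(0, 11), rubric$kind),
    "1" = stats::setNames(rubric$standard_minutes + 1, rubric$kind),
    "0" = NULL
  )
  make_record(id, category, times, ...)
}

# Explicit mean-based sums over all cells; independent of rcb_anova().
brute_force_rcb <- function(m) {
  a <- ncol(m); b <- nrow(m)
  grand <- sum(m) / (a * b)
  ss_t <- 0; ss_b <- 0; ss_tot <- 0
  for (j in seq_len(a)) {
    cm <- sum(m[, j]) / b
    for (i in seq_len(b)) ss_t <- ss_t + (cm - grand)^2
  }
  for (i in seq_len(b)) {
    rm_ <- sum(m[i, ]) / a
    for (j in seq_len(a)) ss_b <- ss_b + (rm_ - grand)^2
  }
  for (i in seq_len(b)) for (j in seq_len(a)) {
    ss_tot <- ss_tot + (m[i, j] - grand)^2
  }
  list(ss_treat = ss_t, ss_block = ss_b, ss_error = ss_tot - ss_t - ss_b,
       ss_total = ss_tot)
}
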