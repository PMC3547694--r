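# Domain types for major-incident command-and-control logs and the
# JSON-lines / flat-CSV log formats.

#' Incident categories
#'
#' The nine categories used to classify declared major incidents: casualty
#' incidents (accidents, threats, fires, CBRNE events) and incidents with
#' other characteristics (hospital-infrastructure interference, infectious
#' events, weather alerts, support to another region, incidents abroad with
#' regional impact).
#'
#' @return Character vector of the 9 category labels.
#' @export
incident_categories <- function() {
  c("accident", "threat", "fire", "hospital_infrastructure", "cbrne",
    "infectious", "weather_alert", "support_other_region", "incident_abroad")
}

#' Decision kinds
#'
#' The 11 decision-event kinds, one per performance indicator, in indicator-id
#' order (indicator 1 first).
#'
#' @return Character vector of 11 decision-kind labels.
#' @export
decision_kinds <- function() {
  c("declare_major_incident", "set_staff_alert_level",
    "send_additional_resources", "designate_receiving_hospitals",
    "contact_scene_command", "preliminary_referral_decision",
    "first_media_information", "formulate_response_guidelines",
    "confirm_referral_information", "assess_own_resources",
    "notify_referral_decision")
}

#' Staffing extents
#'
#' The four levels of regional medical command-and-control staffing: the
#' designated duty officer (DDO) alone, DDO plus a regional medical officer,
#' additional staff functions, or a full regional management group.
#'
#' @return Character vector of 4 staffing-extent labels.
#' @export
staffing_extents <- function() {
  c("ddo_only", "ddo_plus_regional_mo", "plus_staff_functions",
    "full_management_group")
}

#' Construct a decision event
#'
#' @param kind One of [decision_kinds()].
#' @param minutes Minutes from alert (non-negative), or `NA` when the decision
#'   is documented without a usable timestamp.
#' @param note Optional free-text note.
#' @return A `decision_event` list with fields `kind`, `minutes`,
#'   `timestamp_present`, `note`.
#' @export
decision_event <- function(kind, minutes = NA_real_, note = NULL) {
  kind <- as.character(kind)
  if (!kind %in% decision_kinds()) {
    stop("unknown decision kind: ", kind, call. = FALSE)
  }
  minutes <- as.numeric(minutes)
  timestamp_present <- !is.na(minutes)
  if (timestamp_present && minutes < 0) {
    stop("negative minutes-from-alert for event ", kind, call. = FALSE)
  }
  structure(
    list(kind = kind, minutes = minutes,
         timestamp_present = timestamp_present,
         note = if (is.null(note)) NA_character_ else as.character(note)),
    class = "decision_event"
  )
}

#' Construct an incident record
#'
#' One declared major incident's coded log: its category, alert time, the
#' decision events documented by regional command and control, the staffing
#' extent reached, and how long the command function stayed active. Duplicate
#' events of one kind are collapsed to the earliest timestamped one (with a
#' warning), since the rubric asks when a decision was first made.
#'
#' @param incident_id Unique identifier string.
#' @param category One of [incident_categories()].
#' @param alert_time Alert datetime (`POSIXct`, stored in UTC) or an ISO 8601
#'   string.
#' @param events List of [decision_event()] objects.
#' @param staffing_extent One of [staffing_extents()].
#' @param active_minutes Non-negative duration of command activation.
#' @param casualties,receiving_hospitals Optional non-negative integers.
#' @param hospital_plan_activated Optional logical.
#' @param applicable_override Optional logical; when not `NA` it overrides the
#'   category-based applicability rule (see [classify_applicability()]).
#' @return An `incident_record` object.
#' @export
incident_record <- function(incident_id, category, alert_time, events = list(),
                            staffing_extent = "ddo_only", active_minutes = 0,
                            casualties = NA_integer_,
                            receiving_hospitals = NA_integer_,
                            hospital_plan_activated = NA,
                            applicable_override = NA) {
  category <- as.character(category)
  if (!category %in% incident_categories()) {
    stop("unknown incident category: ", category, call. = FALSE)
  }
  staffing_extent <- as.character(staffing_extent)
  if (!staffing_extent %in% staffing_extents()) {
    stop("unknown staffing extent: ", staffing_extent, call. = FALSE)
  }
  alert_time <- parse_iso_time(alert_time)
  active_minutes <- as.numeric(active_minutes)
  if (is.na(active_minutes) || active_minutes < 0) {
    stop("active_minutes must be non-negative", call. = FALSE)
  }
  events <- collapse_duplicate_events(events, incident_id)
  structure(
    list(incident_id = as.character(incident_id), category = category,
         alert_time = alert_time, events = events,
         staffing_extent = staffing_extent, active_minutes = active_minutes,
         casualties = as.integer(casualties),
         receiving_hospitals = as.integer(receiving_hospitals),
         hospital_plan_activated = as.logical(hospital_plan_activated),
         applicable_override = as.logical(applicable_override)),
    class = "incident_record"
  )
}

# Keep the earliest timestamped event per kind; a timestamped event beats a
# timeless one of the same kind.
collapse_duplicate_events <- function(events, incident_id) {
  if (length(events) == 0L) return(list())
  kinds <- vapply(events, function(e) e$kind, character(1))
  if (!anyDuplicated(kinds)) return(events)
  warning("duplicate decision events in incident ", incident_id,
          "; keeping earliest per kind", call. = FALSE)
  kept <- lapply(unique(kinds), function(k) {
    same <- events[kinds == k]
    mins <- vapply(same, function(e) {
      if (e$timestamp_present) e$minutes else Inf
    }, numeric(1))
    same[[which.min(mins)]]
  })
  kept
}

# ISO 8601 parsing normalized to UTC. Accepts "Z" or +-hh:mm / +-hhmm offsets;
# bare datetimes are taken as UTC.
parse_iso_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  x1 <- sub("Z$", "+0000", x)
  x1 <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", x1)
  has_offset <- grepl("[+-]\\d{4}$", x1)
  fmt <- if (has_offset) "%Y-%m-%dT%H:%M:%OS%z" else "%Y-%m-%dT%H:%M:%OS"
  out <- as.POSIXct(x1, format = fmt, tz = "UTC")
  if (any(is.na(out))) {
    stop("unparseable ISO 8601 datetime: ", x[is.na(out)][1], call. = FALSE)
  }
  out
}

format_iso_time <- function(t) {
  format(t, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Minutes from alert to a decision of a given kind
#'
#' @param record An [incident_record()].
#' @param kind One of [decision_kinds()].
#' @return Non-negative minutes if the decision is documented with a time;
#'   `"absent"` if no such decision was documented; `"present_without_time"`
#'   if it was documented but carries no usable timestamp.
#' @export
elapsed_minutes <- function(record, kind) {
  stopifnot(inherits(record, "incident_record"))
  if (!kind %in% decision_kinds()) {
    stop("unknown decision kind: ", kind, call. = FALSE)
  }
  for (e in record$events) {
    if (e$kind == kind) {
      if (!e$timestamp_present) return("present_without_time")
      return(e$minutes)
    }
  }
  "absent"
}

#' Read a JSON-lines incident log
#'
#' One incident per line. Event times may be given as absolute ISO 8601
#' datetimes (`time`) or as minutes from alert (`minutes`); both are
#' normalized to minutes from alert on read, and all datetimes are normalized
#' to UTC.
#'
#' @param path File path, or a character vector of JSON lines.
#' @return List of [incident_record()] objects.
#' @export
read_incident_log <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    path
  }
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        stop("malformed JSON on line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    records[[i]] <- tryCatch(
      record_from_list(rec),
      error = function(e) {
        stop("invalid record on line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    ids[i] <- records[[i]]$incident_id
  }
  if (anyDuplicated(ids)) {
    stop("duplicate incident_id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  records
}

record_from_list <- function(rec) {
  alert <- parse_iso_time(rec$alert_time)
  events <- lapply(rec$events, function(ev) {
    minutes <- if (!is.null(ev$minutes)) {
      as.numeric(ev$minutes)
    } else if (!is.null(ev$time)) {
      as.numeric(difftime(parse_iso_time(ev$time), alert, units = "mins"))
    } else {
      NA_real_
    }
    decision_event(ev$kind, minutes, ev$note)
  })
  opt <- function(x, default) if (is.null(x)) default else x
  incident_record(
    incident_id = rec$incident_id, category = rec$category,
    alert_time = alert, events = events,
    staffing_extent = opt(rec$staffing_extent, "ddo_only"),
    active_minutes = opt(rec$active_minutes, 0),
    casualties = opt(rec$casualties, NA_integer_),
    receiving_hospitals = opt(rec$receiving_hospitals, NA_integer_),
    hospital_plan_activated = opt(rec$hospital_plan_activated, NA),
    applicable_override = opt(rec$applicable_override, NA)
  )
}

#' Write a JSON-lines incident log
#'
#' Event times are written as minutes from alert (1-second resolution);
#' datetimes are written as UTC ISO 8601. Writing then reading reproduces all
#' fields.
#'
#' @param records List of [incident_record()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_incident_log <- function(records, path) {
  lines <- vapply(records, function(r) {
    events <- lapply(r$events, function(e) {
      ev <- list(kind = e$kind)
      if (e$timestamp_present) ev$minutes <- round(e$minutes * 60) / 60
      if (!is.na(e$note)) ev$note <- e$note
      ev
    })
    x <- list(incident_id = r$incident_id, category = r$category,
              alert_time = format_iso_time(r$alert_time), events = events,
              staffing_extent = r$staffing_extent,
              active_minutes = r$active_minutes)
    if (!is.na(r$casualties)) x$casualties <- r$casualties
    if (!is.na(r$receiving_hospitals)) {
      x$receiving_hospitals <- r$receiving_hospitals
    }
    if (!is.na(r$hospital_plan_activated)) {
      x$hospital_plan_activated <- r$hospital_plan_activated
    }
    if (!is.na(r$applicable_override)) {
      x$applicable_override <- r$applicable_override
    }
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write the flat CSV incident-log dialect
#'
#' One row per decision event with the incident header columns repeated;
#' incidents without events appear as a single row with an empty
#' `event_kind`. Vocabulary and semantics are identical to the JSON-lines
#' format.
#'
#' @param path CSV file path.
#' @return `read_incident_csv()`: list of [incident_record()] objects.
#' @export
read_incident_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  needed <- c("incident_id", "category", "alert_time", "staffing_extent",
              "active_minutes", "event_kind", "event_minutes")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("CSV log missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  ids <- unique(df$incident_id)
  records <- lapply(ids, function(id) {
    rows <- df[df$incident_id == id, , drop = FALSE]
    h <- rows[1, ]
    ev_rows <- rows[nzchar(rows$event_kind), , drop = FALSE]
    events <- lapply(seq_len(nrow(ev_rows)), function(i) {
      note <- if ("event_note" %in% names(ev_rows) &&
                  nzchar(ev_rows$event_note[i])) ev_rows$event_note[i]
      decision_event(ev_rows$event_kind[i], num_or_na(ev_rows$event_minutes[i]),
                     note)
    })
    getcol <- function(col, coerce, default) {
      if (col %in% names(h) && nzchar(h[[col]])) coerce(h[[col]]) else default
    }
    incident_record(
      incident_id = id, category = h$category, alert_time = h$alert_time,
      events = events, staffing_extent = h$staffing_extent,
      active_minutes = as.numeric(h$active_minutes),
      casualties = getcol("casualties", as.integer, NA_integer_),
      receiving_hospitals = getcol("receiving_hospitals", as.integer,
                                   NA_integer_),
      hospital_plan_activated = getcol("hospital_plan_activated", as.logical,
                                       NA),
      applicable_override = getcol("applicable_override", as.logical, NA)
    )
  })
  records
}

#' @rdname read_incident_csv
#' @param records List of [incident_record()] objects.
#' @return `write_incident_csv()`: `path`, invisibly.
#' @export
write_incident_csv <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    base <- data.frame(
      incident_id = r$incident_id, category = r$category,
      alert_time = format_iso_time(r$alert_time),
      staffing_extent = r$staffing_extent, active_minutes = r$active_minutes,
      casualties = if (is.na(r$casualties)) "" else r$casualties,
      receiving_hospitals = if (is.na(r$receiving_hospitals)) "" else
        r$receiving_hospitals,
      hospital_plan_activated = if (is.na(r$hospital_plan_activated)) "" else
        r$hospital_plan_activated,
      applicable_override = if (is.na(r$applicable_override)) "" else
        r$applicable_override,
      stringsAsFactors = FALSE
    )
    if (length(r$events) == 0L) {
      return(cbind(base, event_kind = "", event_minutes = "", event_note = ""))
    }
    ev <- do.call(rbind, lapply(r$events, function(e) {
      data.frame(
        event_kind = e$kind,
        event_minutes = if (e$timestamp_present) {
          as.character(round(e$minutes * 60) / 60)
        } else "",
        event_note = if (is.na(e$note)) "" else e$note,
        stringsAsFactors = FALSE
      )
    }))
    cbind(base[rep(1, nrow(ev)), , drop = FALSE], ev)
  }))
  rownames(rows) <- NULL
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
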