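test_that("vocabularies have the expected structure", {
  expect_length(unique(incident_categories()), 9)
  expect_length(unique(decision_kinds()), 11)
  expect_length(unique(staffing_extents()), 4)
})

test_that("parsing maps fields directly and normalizes times to minutes", {
  line <- paste0('{"incident_id":"A1","category":"accident",',
                 '"alert_time":"2006-03-01T10:00:00Z",',
                 '"events":[{"kind":"declare_major_incident",',
                 '"time":"2006-03-01T10:00:30Z"}],',
                 '"staffing_extent":"ddo_only","active_minutes":45}')
  recs <- read_incident_log(line)
  expect_length(recs, 1)
  expect_equal(elapsed_minutes(recs[[1]], "declare_major_incident"), 0.5)
  expect_equal(recs[[1]]$category, "accident")
  expect_equal(recs[[1]]$active_minutes, 45)
})

test_that("empty stream yields an empty cohort", {
  expect_length(read_incident_log(character(0)), 0)
})

test_that("unknown event kinds, bad times and duplicate ids are rejected", {
  expect_error(decision_event("coffee_break"), "unknown decision kind")
  expect_error(
    read_incident_log(paste0('{"incident_id":"A1","category":"accident",',
      '"alert_time":"2006-03-01T10:00:00Z",',
      '"events":[{"kind":"coffee_break","minutes":3}]}')),
    "unknown decision kind")
  expect_error(decision_event("declare_major_incident", -2), "negative")
  two <- paste0('{"incident_id":"A1","category":"accident",',
                '"alert_time":"2006-03-01T10:00:00Z","events":[]}')
  expect_error(read_incident_log(c(two, two)), "duplicate incident_id")
  expect_error(read_incident_log('{"incident_id":'), "line 1")
})

test_that("elapsed_minutes distinguishes absent from timeless decisions", {
  r <- make_record(times = c(designate_receiving_hospitals = 7,
                             first_media_information = NA))
  expect_equal(elapsed_minutes(r, "designate_receiving_hospitals"), 7)
  expect_identical(elapsed_minutes(r, "formulate_response_guidelines"),
                   "absent")
  expect_identical(elapsed_minutes(r, "first_media_information"),
                   "present_without_time")
})

test_that("elapsed time is the same for absolute and minutes encodings", {
  abs_line <- paste0('{"incident_id":"A1","category":"fire",',
    '"alert_time":"2006-03-01T10:00:00+01:00",',
    '"events":[{"kind":"contact_scene_command",',
    '"time":"2006-03-01T10:12:30+01:00"}]}')
  min_line <- paste0('{"incident_id":"A1","category":"fire",',
    '"alert_time":"2006-03-01T09:00:00Z",',
    '"events":[{"kind":"contact_scene_command","minutes":12.5}]}')
  r_abs <- read_incident_log(abs_line)[[1]]
  r_min <- read_incident_log(min_line)[[1]]
  expect_equal(elapsed_minutes(r_abs, "contact_scene_command"),
               elapsed_minutes(r_min, "contact_scene_command"))
  # offsets are normalized to UTC
  expect_equal(r_abs$alert_time, r_min$alert_time)
})

test_that("duplicate events of one kind keep the earliest, with warning", {
  expect_warning(
    r <- incident_record(
      incident_id = "A1", category = "accident",
      alert_time = "2006-01-01T10:00:00Z",
      events = list(
        decision_event("declare_major_incident", 5),
        decision_event("declare_major_incident", 2),
        decision_event("declare_major_incident", NA))),
    "duplicate")
  expect_equal(elapsed_minutes(r, "declare_major_incident"), 2)
})

test_that("JSON-lines and CSV round trips reproduce all fields", {
  set.seed(42)
  cohort <- generate_cohort(calibration_preset(), seed = 7)[1:12]
  # add a timeless event and optional-field variety
  cohort[[1]]$events[[1]] <- decision_event("assess_own_resources", NA)
  for (path_fun in list(
    list(write = write_incident_log, read = read_incident_log,
         ext = ".jsonl"),
    list(write = write_incident_csv, read = read_incident_csv,
         ext = ".csv"))) {
    path <- tempfile(fileext = path_fun$ext)
    path_fun$write(cohort, path)
    back <- path_fun$read(path)
    expect_length(back, length(cohort))
    for (k in seq_along(cohort)) {
      orig <- cohort[[k]]
      got <- back[[k]]
      expect_equal(got$incident_id, orig$incident_id)
      expect_equal(got$category, orig$category)
      expect_equal(as.numeric(got$alert_time), as.numeric(orig$alert_time))
      expect_equal(got$staffing_extent, orig$staffing_extent)
      expect_equal(got$active_minutes, orig$active_minutes)
      expect_equal(got$casualties, orig$casualties)
      expect_equal(got$applicable_override, orig$applicable_override)
      expect_length(got$events, length(orig$events))
      for (e in seq_along(orig$events)) {
        expect_equal(got$events[[e]]$kind, orig$events[[e]]$kind)
        expect_equal(got$events[[e]]$timestamp_present,
                     orig$events[[e]]$timestamp_present)
        if (orig$events[[e]]$timestamp_present) {
          # 1-second resolution
          expect_lte(abs(got$events[[e]]$minutes - orig$events[[e]]$minutes),
                     0.5 / 60 + 1e-9)
        }
      }
    }
  }
})
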