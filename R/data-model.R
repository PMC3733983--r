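# Domain vocabulary: controlled values for the long events table.

.settings <- c("inpatient", "outpatient", "emergency_urgent")
.event_kinds <- c("encounter_dx", "lab", "medication", "history")
.test_kinds <- c("hba1c", "fasting_glucose", "random_glucose", "ogtt_2h")
.med_classes <- c("metformin", "other_diabetes_medication",
                  "non_diabetes_medication")
.history_sources <- c("problem_list", "past_medical_history")
.sexes <- c("male", "female", "other_unknown")
.payers <- c("commercial", "medicare", "medicaid", "self_pay", "charity",
             "other")
.categories <- c("none", "possible", "diabetes")

.event_cols <- c("patient_id", "date", "setting", "kind", "code",
                 "test_kind", "value", "units", "med_class",
                 "history_source")
.patient_cols <- c("patient_id", "birth_date", "sex", "payer")

#' Ordered three-way diabetes categories
#'
#' Returns the ordered category labels used throughout the package:
#' `"none"` (0 points), `"possible"` (between 0 and the diagnostic
#' threshold), `"diabetes"` (at or above the threshold).
#'
#' @return Character vector of length 3, in increasing order of evidence.
#' @export
dm_categories <- function() .categories

# ICD-9-CM lexical shape: optional V/E prefix, 1-3 digits, optional dot and
# up to two more digits. "2500" (no dot) is not a category-level 250 code.
.is_icd9 <- function(code) {
  grepl("^[VvEe]?[0-9]{1,3}(\\.[0-9]{0,2})?$", code)
}

# Category-level prefix match: "250", "250.0", "250.00" all match prefix
# "250"; "2500" and "25.0" do not.
.icd9_category_match <- function(code, prefix) {
  !is.na(code) & (code == prefix | startsWith(code, paste0(prefix, ".")))
}

.expected_units <- c(hba1c = "%", fasting_glucose = "mg/dL",
                     random_glucose = "mg/dL", ogtt_2h = "mg/dL")

#' Construct an empty events table
#'
#' @return A zero-row tibble with the canonical event columns.
#' @export
empty_events <- function() {
  tibble::tibble(
    patient_id = character(), date = as.Date(character()),
    setting = character(), kind = character(), code = character(),
    test_kind = character(), value = double(), units = character(),
    med_class = character(), history_source = character()
  )
}

#' Construct an empty patients table
#'
#' @return A zero-row tibble with the canonical patient columns.
#' @export
empty_patients <- function() {
  tibble::tibble(
    patient_id = character(), birth_date = as.Date(character()),
    sex = character(), payer = character()
  )
}

# Per-row semantic validation of a parsed events tibble. Returns a tibble of
# row-level problems (line = 1-based data row number).
.validate_event_rows <- function(ev) {
  problems <- list()
  note <- function(line, message) {
    problems[[length(problems) + 1L]] <<- tibble::tibble(
      line = line, message = message)
  }
  for (i in seq_len(nrow(ev))) {
    row <- ev[i, ]
    if (is.na(row$patient_id) || !nzchar(row$patient_id)) {
      note(i, "missing patient_id"); next
    }
    if (is.na(row$date)) {
      note(i, "unparseable or missing date"); next
    }
    if (is.na(row$setting) || !row$setting %in% .settings) {
      note(i, sprintf("unknown setting '%s'", row$setting)); next
    }
    if (is.na(row$kind) || !row$kind %in% .event_kinds) {
      note(i, sprintf("unknown event kind '%s'", row$kind)); next
    }
    switch(row$kind,
      encounter_dx = {
        if (is.na(row$code) || !.is_icd9(row$code))
          note(i, sprintf("invalid ICD-9 code '%s'", row$code))
      },
      lab = {
        if (is.na(row$test_kind) || !row$test_kind %in% .test_kinds) {
          note(i, sprintf("unknown test_kind '%s'", row$test_kind))
        } else if (is.na(row$value) || row$value <= 0) {
          note(i, "lab value missing or non-positive")
        } else if (!is.na(row$units) && nzchar(row$units) &&
                   row$units != .expected_units[[row$test_kind]]) {
          note(i, sprintf("units '%s' inconsistent with test_kind '%s'",
                          row$units, row$test_kind))
        }
      },
      medication = {
        if (is.na(row$med_class) || !row$med_class %in% .med_classes)
          note(i, sprintf("unknown med_class '%s'", row$med_class))
      },
      history = {
        if (is.na(row$history_source) ||
            !row$history_source %in% .history_sources) {
          note(i, sprintf("unknown history_source '%s'", row$history_source))
        } else if (is.na(row$code) || !.is_icd9(row$code)) {
          note(i, sprintf("invalid ICD-9 code '%s'", row$code))
        }
      }
    )
  }
  if (length(problems) == 0L) {
    tibble::tibble(line = integer(), message = character())
  } else {
    dplyr::bind_rows(problems)
  }
}

#' Read an EHR events table from CSV
#'
#' Reads the long-format events file (one row per dated clinical fact).
#' Required columns: `patient_id, date, setting, kind, code, test_kind,
#' value, units, med_class, history_source`; unused payload columns are
#' empty per row. Dates must be ISO-8601 calendar dates. Malformed rows are
#' collected into an error report (attached as the `"errors"` attribute and
#' surfaced via a warning), never silently dropped from the count.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A tibble of valid events, sorted by `patient_id` then `date`
#'   (stable within a date), with attribute `errors`: a tibble of
#'   `(line, message)` for rejected rows (line numbers are 1-based data
#'   rows, excluding the header).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("events file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(.event_cols, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("events file is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  ev <- tibble::tibble(
    patient_id = raw$patient_id,
    date = as.Date(raw$date, format = "%Y-%m-%d"),
    setting = raw$setting,
    kind = raw$kind,
    code = raw$code,
    test_kind = raw$test_kind,
    value = suppressWarnings(as.numeric(raw$value)),
    units = raw$units,
    med_class = raw$med_class,
    history_source = raw$history_source
  )
  errors <- .validate_event_rows(ev)
  if (nrow(errors) > 0L) {
    ev <- ev[-errors$line, ]
    warn(sprintf("%d malformed event row(s) rejected; see attr(x, 'errors')",
                 nrow(errors)))
  }
  ev <- .sort_events(ev)
  attr(ev, "errors") <- errors
  ev
}

# Stable sort: patient, then date, preserving input order within a date.
.sort_events <- function(ev) {
  ev[order(ev$patient_id, ev$date), , drop = FALSE]
}

#' Write an events table to CSV
#'
#' Inverse of [read_events()]: `read_events(write_events(ev, p))` reproduces
#' the events field-for-field.
#'
#' @param events Events tibble (canonical columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- events[, .event_cols]
  out$date <- format(out$date, "%Y-%m-%d")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a patients table from CSV
#'
#' Columns: `patient_id, birth_date, sex, payer` (`payer` may be empty).
#'
#' @param path Path to a UTF-8 CSV file.
#' @return Tibble of patients.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) abort(sprintf("patients file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(.patient_cols, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("patients file is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  tibble::tibble(
    patient_id = raw$patient_id,
    birth_date = as.Date(raw$birth_date, format = "%Y-%m-%d"),
    sex = raw$sex,
    payer = raw$payer
  )
}

#' Write a patients table to CSV
#'
#' @param patients Patients tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  out <- patients[, .patient_cols]
  out$birth_date <- format(out$birth_date, "%Y-%m-%d")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read gold-standard labels from CSV
#'
#' Columns: `patient_id`, `gold_category` in `none/possible/diabetes`,
#' `gold_date` (empty unless `gold_category == "diabetes"`).
#'
#' @param path Path to a UTF-8 CSV file.
#' @return Tibble of gold labels.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) abort(sprintf("gold file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(c("patient_id", "gold_category", "gold_date"),
                     names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("gold file is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad <- !raw$gold_category %in% .categories
  if (any(bad)) {
    abort(sprintf("unknown gold_category value(s): %s",
                  paste(unique(raw$gold_category[bad]), collapse = ", ")))
  }
  tibble::tibble(
    patient_id = raw$patient_id,
    gold_category = raw$gold_category,
    gold_date = as.Date(raw$gold_date, format = "%Y-%m-%d")
  )
}

#' Write gold-standard labels to CSV
#'
#' @param gold Gold-label tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  out <- gold[, c("patient_id", "gold_category", "gold_date")]
  out$gold_date <- format(out$gold_date, "%Y-%m-%d")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Assemble an EHR cohort from patients and events
#'
#' Bundles a patients table and an events table into a validated cohort:
#' patient ids are unique, every event belongs to a listed patient (when a
#' patients table is supplied), events are date-sorted per patient, and no
#' event precedes its patient's birth date.
#'
#' @param patients Patients tibble, or `NULL` to derive a minimal patients
#'   table from the distinct `patient_id`s in `events`.
#' @param events Events tibble.
#' @return An object of class `ehr_cohort`: a list with elements `patients`
#'   and `events`.
#' @export
ehr_cohort <- function(patients = NULL, events = empty_events()) {
  if (is.null(patients)) {
    patients <- tibble::tibble(
      patient_id = unique(events$patient_id),
      birth_date = as.Date(NA), sex = NA_character_, payer = NA_character_)
  }
  if (anyDuplicated(patients$patient_id)) {
    dup <- unique(patients$patient_id[duplicated(patients$patient_id)])
    abort(sprintf("duplicate patient_id in cohort: %s",
                  paste(dup, collapse = ", ")))
  }
  orphan <- setdiff(unique(events$patient_id), patients$patient_id)
  if (length(orphan) > 0L) {
    abort(sprintf("events reference unknown patient_id(s): %s",
                  paste(head(orphan, 5L), collapse = ", ")))
  }
  if (nrow(events) > 0L && any(!is.na(patients$birth_date))) {
    first_event <- events |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(first = min(.data$date), .groups = "drop")
    chk <- dplyr::inner_join(first_event, patients, by = "patient_id")
    bad <- !is.na(chk$birth_date) & chk$first < chk$birth_date
    if (any(bad)) {
      abort(sprintf("event(s) precede birth_date for patient(s): %s",
                    paste(head(chk$patient_id[bad], 5L), collapse = ", ")))
    }
  }
  structure(list(patients = patients, events = .sort_events(events)),
            class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf("<ehr_cohort> %d patient(s), %d event(s)\n",
              nrow(x$patients), nrow(x$events)))
  invisible(x)
}

#' Extract one patient's timeline from a cohort
#'
#' @param cohort An `ehr_cohort`.
#' @param patient_id A single patient id.
#' @return The patient's events, date-sorted.
#' @export
patient_timeline <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (!patient_id %in% cohort$patients$patient_id) {
    abort(sprintf("unknown patient_id: %s", patient_id))
  }
  cohort$events[cohort$events$patient_id == patient_id, , drop = FALSE]
}

# Row constructors used by the generator, tests and examples. Each returns a
# one-row canonical events tibble.

#' Construct single EHR event rows
#'
#' Convenience constructors returning one-row event tibbles in the canonical
#' long format, used to assemble timelines programmatically.
#'
#' @param patient_id Patient identifier.
#' @param date Event date (`Date` or ISO-8601 string).
#' @param setting Care setting: `"inpatient"`, `"outpatient"`, or
#'   `"emergency_urgent"`.
#' @param code ICD-9-CM code string (e.g. `"250.00"`).
#' @param test_kind Lab test kind: `"hba1c"`, `"fasting_glucose"`,
#'   `"random_glucose"`, or `"ogtt_2h"`.
#' @param value Numeric lab result (`%` for HbA1c, mg/dL for glucoses).
#' @param med_class `"metformin"`, `"other_diabetes_medication"`, or
#'   `"non_diabetes_medication"`.
#' @param source `"problem_list"` or `"past_medical_history"`.
#' @return A one-row events tibble.
#' @name event-constructors
NULL

.event_row <- function(patient_id, date, setting, kind, code = NA_character_,
                       test_kind = NA_character_, value = NA_real_,
                       units = NA_character_, med_class = NA_character_,
                       history_source = NA_character_) {
  tibble::tibble(
    patient_id = patient_id, date = as.Date(date), setting = setting,
    kind = kind, code = code, test_kind = test_kind, value = value,
    units = units, med_class = med_class, history_source = history_source)
}

#' @rdname event-constructors
#' @export
encounter_event <- function(patient_id, date, code, setting = "outpatient") {
  .event_row(patient_id, date, setting, "encounter_dx", code = code)
}

#' @rdname event-constructors
#' @export
lab_event <- function(patient_id, date, test_kind, value,
                      setting = "outpatient") {
  .event_row(patient_id, date, setting, "lab", test_kind = test_kind,
             value = value, units = .expected_units[[test_kind]])
}

#' @rdname event-constructors
#' @export
medication_event <- function(patient_id, date, med_class,
                             setting = "outpatient") {
  .event_row(patient_id, date, setting, "medication", med_class = med_class)
}

#' @rdname event-constructors
#' @export
history_event <- function(patient_id, date, code, source = "problem_list",
                          setting = "outpatient") {
  .event_row(patient_id, date, setting, "history", code = code,
             history_source = source)
}
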