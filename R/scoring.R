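# The scoring engine: criterion matching, chronological point accrual,
# three-way classification, earliest-diagnosis-date determination.

# Map one event row to the name of the criterion that could score it, or NA.
.candidate_criterion <- function(kind, test_kind, med_class) {
  if (kind == "encounter_dx") return("icd9_encounter")
  if (kind == "lab") return(test_kind)
  if (kind == "medication") {
    if (is.na(med_class)) return(NA_character_)
    return(switch(med_class,
                  metformin = "metformin",
                  other_diabetes_medication = "diabetes_medication",
                  NA_character_))
  }
  if (kind == "history") return("history_dx")
  NA_character_
}

# Annotate events with the matching criterion and its centipoint weight.
# Returns the events tibble plus columns `criterion` (NA when unmatched) and
# `points_centi`. Unit mismatches abort: silent unit conversion would make a
# 6.5 look like 6.5 mg/dL.
.match_events <- function(events, config) {
  n <- nrow(events)
  criterion <- rep(NA_character_, n)
  points_centi <- rep(NA_integer_, n)
  crit <- config$criteria
  for (i in seq_len(n)) {
    cand <- .candidate_criterion(events$kind[i], events$test_kind[i],
                                 events$med_class[i])
    if (is.na(cand)) next
    j <- which(crit$name == cand)
    if (length(j) == 0L) next
    if (!events$setting[i] %in% crit$allowed_settings[[j]]) next
    if (!is.na(crit$threshold[j])) {
      u <- events$units[i]
      if (!is.na(u) && nzchar(u) && !is.na(crit$units[j]) &&
          u != crit$units[j]) {
        abort(sprintf(
          "units '%s' inconsistent with criterion '%s' (expects '%s') for patient %s on %s",
          u, cand, crit$units[j], events$patient_id[i],
          format(events$date[i])))
      }
      if (is.na(events$value[i]) || events$value[i] < crit$threshold[j]) next
    }
    if (!is.na(crit$code_prefix[j])) {
      if (!.icd9_category_match(events$code[i], crit$code_prefix[j])) next
    }
    criterion[i] <- cand
    points_centi[i] <- crit$weight_centi[j]
  }
  events$criterion <- criterion
  events$points_centi <- points_centi
  events
}

#' Match a single event against the scoring configuration
#'
#' Determines whether one EHR event qualifies under any criterion: ICD-9
#' matching is a category-level prefix match on 250 (codes `250`, `250.0`,
#' `250.00`, ... qualify; dotless strings like `2500` do not); lab
#' thresholds are inclusive (`>=`) in the configured units; an event whose
#' care setting is outside the criterion's allowed settings does not match.
#'
#' @param event A one-row events tibble.
#' @param config A `weight_config` (default [default_config()]).
#' @return `NULL` if the event matches no criterion, else a list with
#'   `criterion` (name) and `points` (its weight).
#' @export
match_event <- function(event, config = default_config()) {
  stopifnot(is.data.frame(event), nrow(event) == 1L)
  m <- .match_events(tibble::as_tibble(event), config)
  if (is.na(m$criterion)) return(NULL)
  list(criterion = m$criterion, points = m$points_centi / 100)
}

#' Classify a cumulative point total
#'
#' Three-way classification from a point total: `"none"` at exactly 0,
#' `"possible"` strictly between 0 and the diagnostic threshold, and
#' `"diabetes"` at or above the threshold (default 1 point).
#'
#' @param total Non-negative point total(s); vectorised.
#' @param config A `weight_config`.
#' @return Character vector of categories.
#' @export
classify_total <- function(total, config = default_config()) {
  if (any(total < 0)) abort("point totals must be non-negative")
  centi <- round(total * 100)
  dplyr::case_when(
    centi >= config$threshold_centi ~ "diabetes",
    centi > 0 ~ "possible",
    TRUE ~ "none"
  )
}

# Apply accrual policy to matched contributions for one patient. Input rows
# are in timeline order (date-sorted). per_distinct_date keeps one
# contribution per (criterion, date); once_per_patient keeps only the first
# qualifying date per criterion. Same-date input order cannot change the
# result: survivors are keyed by (criterion, date) and all rows for a given
# key carry the same weight.
.accrue <- function(matched, config) {
  m <- matched[!is.na(matched$criterion), , drop = FALSE]
  if (nrow(m) == 0L) {
    return(tibble::tibble(date = as.Date(character()),
                          criterion = character(),
                          points_centi = integer()))
  }
  m <- m[order(m$date), , drop = FALSE]
  policy <- setNames(config$criteria$accrual, config$criteria$name)
  keep_date <- !duplicated(paste(m$criterion, m$date))
  keep_first <- !duplicated(m$criterion)
  once <- policy[m$criterion] == "once_per_patient"
  m <- m[ifelse(once, keep_first, keep_date), , drop = FALSE]
  out <- m[, c("date", "criterion", "points_centi")]
  out[order(out$date, out$criterion), , drop = FALSE]
}

#' Score one patient timeline
#'
#' Walks a patient's events in date order, accrues points per the
#' configuration's accrual policies (labs and encounter codes contribute at
#' most once per criterion per calendar date; history, diabetes-medication
#' and metformin criteria contribute only once per patient), classifies the
#' cumulative total, and determines the earliest diagnosis date: the first
#' calendar date on which the accumulated total reaches the diagnostic
#' threshold. Deterministic and independent of same-date input order.
#'
#' @param timeline Events tibble for a single patient (any row order;
#'   sorted internally).
#' @param config A `weight_config`.
#' @param patient_id Optional id override for an empty timeline.
#' @return A `patient_score` list: `patient_id`, `total` (points),
#'   `category`, `diagnosis_date` (`NA` unless category is `"diabetes"`),
#'   and a `contributions` tibble (`date, criterion, points`).
#' @examples
#' tl <- rbind(lab_event("p1", "2009-03-01", "fasting_glucose", 130),
#'             lab_event("p1", "2009-05-01", "fasting_glucose", 141))
#' score_patient(tl)  # total 1, diabetes, diagnosed 2009-05-01
#' @export
score_patient <- function(timeline, config = default_config(),
                          patient_id = NULL) {
  stopifnot(inherits(config, "weight_config"))
  if (nrow(timeline) > 0L && length(unique(timeline$patient_id)) > 1L) {
    abort("score_patient expects events for a single patient")
  }
  pid <- if (nrow(timeline) > 0L) timeline$patient_id[[1]]
         else patient_id %||% NA_character_
  contrib <- .accrue(.match_events(timeline, config), config)
  total_centi <- sum(contrib$points_centi)
  category <- classify_total(total_centi / 100, config)
  diagnosis_date <- as.Date(NA)
  if (category == "diabetes") {
    by_date <- contrib |>
      dplyr::group_by(.data$date) |>
      dplyr::summarise(pts = sum(.data$points_centi), .groups = "drop") |>
      dplyr::arrange(.data$date)
    cum <- cumsum(by_date$pts)
    diagnosis_date <- by_date$date[which(cum >= config$threshold_centi)[1]]
  }
  structure(list(
    patient_id = pid,
    total = total_centi / 100,
    category = category,
    diagnosis_date = diagnosis_date,
    contributions = tibble::tibble(date = contrib$date,
                                   criterion = contrib$criterion,
                                   points = contrib$points_centi / 100)
  ), class = "patient_score")
}

#' @export
print.patient_score <- function(x, ...) {
  cat(sprintf("<patient_score> %s: %.2f points -> %s%s\n",
              x$patient_id, x$total, x$category,
              if (!is.na(x$diagnosis_date))
                paste0(" (diagnosed ", format(x$diagnosis_date), ")")
              else ""))
  invisible(x)
}

#' Score every patient in a cohort
#'
#' Applies [score_patient()] to each patient (patients with no events score
#' 0, category `"none"`) and summarises category counts and fractions.
#'
#' @param cohort An `ehr_cohort`, or an events tibble (a minimal cohort is
#'   derived from its distinct patient ids).
#' @param config A `weight_config`.
#' @param audit If `TRUE`, attach the per-contribution audit trail as
#'   attribute `"contributions"` (one row per scored contribution).
#' @return A tibble with columns `patient_id, total_points, category,
#'   diagnosis_date`, with attribute `"summary"`: a tibble of per-category
#'   `n` and `fraction` (fractions sum to 1 on non-empty cohorts).
#' @export
score_cohort <- function(cohort, config = default_config(), audit = FALSE) {
  if (!inherits(cohort, "ehr_cohort")) {
    cohort <- ehr_cohort(events = cohort)
  }
  ids <- cohort$patients$patient_id
  ev_split <- split(cohort$events, factor(cohort$events$patient_id,
                                          levels = ids))
  scores <- lapply(ids, function(id) {
    score_patient(ev_split[[id]], config, patient_id = id)
  })
  out <- tibble::tibble(
    patient_id = ids,
    total_points = vapply(scores, function(s) s$total, double(1)),
    category = vapply(scores, function(s) s$category, character(1)),
    diagnosis_date = as.Date(vapply(scores, function(s)
      as.character(s$diagnosis_date), character(1)))
  )
  counts <- table(factor(out$category, levels = .categories))
  summary <- tibble::tibble(
    category = names(counts),
    n = as.integer(counts),
    fraction = if (nrow(out) > 0L) as.numeric(counts) / nrow(out)
               else rep(NA_real_, length(counts))
  )
  attr(out, "summary") <- summary
  if (audit) {
    attr(out, "contributions") <- dplyr::bind_rows(lapply(scores, function(s)
      dplyr::mutate(s$contributions, patient_id = s$patient_id,
                    .before = 1L)))
  }
  out
}

#' Read / write cohort score tables
#'
#' `scores.csv` interchange: `patient_id, total_points, category,
#' diagnosis_date` (empty unless category is `"diabetes"`).
#'
#' @param scores Scores tibble as returned by [score_cohort()].
#' @param path CSV path.
#' @return `write_scores()` returns `path` invisibly; `read_scores()` the
#'   scores tibble.
#' @export
write_scores <- function(scores, path) {
  out <- scores[, c("patient_id", "total_points", "category",
                    "diagnosis_date")]
  out$diagnosis_date <- format(out$diagnosis_date, "%Y-%m-%d")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) abort(sprintf("scores file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  tibble::tibble(
    patient_id = raw$patient_id,
    total_points = as.numeric(raw$total_points),
    category = raw$category,
    diagnosis_date = as.Date(raw$diagnosis_date, format = "%Y-%m-%d")
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
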