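# Claims-based comparator: two ICD-9 250.xx encounter codes identify
# diabetes; the diagnosis date is the date of the second code.

#' Two-code claims-based comparator
#'
#' The simplified claims-style baseline: a patient is identified as diabetic
#' when they have encounter diagnoses in the ICD-9 250 category on at least
#' two distinct calendar dates (any care setting), and the diagnosis date is
#' the second such date. Codes on the same calendar date are deduplicated
#' (two codes on one visit are one claim) when `dedup_same_date` is `TRUE`,
#' the default. Labs, medications and history entries never contribute.
#'
#' @param timeline Events tibble for a single patient.
#' @param code_prefix ICD-9 category prefix (default `"250"`).
#' @param dedup_same_date Count at most one qualifying code per calendar
#'   date.
#' @return A list of class `claims_result`: `patient_id`, `identified`
#'   (logical), `diagnosis_date` (`NA` unless identified), `n_codes`
#'   (number of qualifying codes after deduplication).
#' @export
claims_two_code <- function(timeline, code_prefix = "250",
                            dedup_same_date = TRUE) {
  pid <- if (nrow(timeline) > 0L) timeline$patient_id[[1]] else NA_character_
  enc <- timeline[timeline$kind == "encounter_dx" &
                    .icd9_category_match(timeline$code, code_prefix), ,
                  drop = FALSE]
  dates <- sort(enc$date)
  if (dedup_same_date) dates <- unique(dates)
  n <- length(dates)
  structure(list(
    patient_id = pid,
    identified = n >= 2L,
    diagnosis_date = if (n >= 2L) dates[[2L]] else as.Date(NA),
    n_codes = n
  ), class = "claims_result")
}

#' @export
print.claims_result <- function(x, ...) {
  cat(sprintf("<claims_result> %s: %s (%d qualifying code date(s))%s\n",
              x$patient_id,
              if (x$identified) "identified" else "not identified",
              x$n_codes,
              if (!is.na(x$diagnosis_date))
                paste0(", diagnosed ", format(x$diagnosis_date)) else ""))
  invisible(x)
}

#' Apply the two-code comparator to a whole cohort
#'
#' @param cohort An `ehr_cohort` or events tibble.
#' @inheritParams claims_two_code
#' @return Tibble with columns `patient_id, identified, diagnosis_date,
#'   n_codes`, one row per patient.
#' @export
claims_cohort <- function(cohort, code_prefix = "250",
                          dedup_same_date = TRUE) {
  if (!inherits(cohort, "ehr_cohort")) cohort <- ehr_cohort(events = cohort)
  ids <- cohort$patients$patient_id
  ev_split <- split(cohort$events, factor(cohort$events$patient_id,
                                          levels = ids))
  res <- lapply(ids, function(id) {
    r <- claims_two_code(ev_split[[id]], code_prefix, dedup_same_date)
    r$patient_id <- id
    r
  })
  tibble::tibble(
    patient_id = ids,
    identified = vapply(res, function(r) r$identified, logical(1)),
    diagnosis_date = as.Date(vapply(res, function(r)
      as.character(r$diagnosis_date), character(1))),
    n_codes = vapply(res, function(r) r$n_codes, integer(1))
  )
}

#' Write claims-comparator results to CSV
#'
#' @param claims Tibble from [claims_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path) {
  out <- claims
  out$diagnosis_date <- format(out$diagnosis_date, "%Y-%m-%d")
  readr::write_csv(out, path, na = "")
  invisible(path)
}
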