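# Seeded synthetic EHR cohort generator with known ground truth.
#
# Each patient is drawn from an archetype that fixes both the generated
# chart and the gold-standard answer: true diabetics (diagnosable from
# labs, from a medication order, or from repeat encounter codes, with the
# gold date constructed as the earliest date the chart evidence suffices)
# and the documented noise modes (metformin for pre-diabetes or polycystic
# ovarian syndrome, stale problem-list entries, an isolated miscoded ICD-9
# encounter) alongside healthy controls.

.archetypes <- c("true_diabetic_labs", "true_diabetic_meds",
                 "true_diabetic_codes", "prediabetic_metformin",
                 "pcos_metformin", "stale_problem_list",
                 "miscoded_single_icd9", "healthy", "healthy_elderly")

# Non-diabetes ICD-9 distractor codes for background encounters.
.distractor_codes <- c("401.9", "272.4", "486", "780.79", "V70.0", "530.81")

#' Default archetype mix
#'
#' A mixed outpatient population: 40% true diabetics (split across the
#' three evidence routes), 20% noise-mode patients, 40% healthy.
#'
#' @return Named numeric vector of proportions summing to 1.
#' @export
default_mix <- function() {
  c(true_diabetic_labs = 0.15, true_diabetic_meds = 0.10,
    true_diabetic_codes = 0.15, prediabetic_metformin = 0.05,
    pcos_metformin = 0.05, stale_problem_list = 0.05,
    miscoded_single_icd9 = 0.05, healthy = 0.30, healthy_elderly = 0.10)
}

#' Specify a synthetic cohort
#'
#' @param n_patients Number of patients (> 0).
#' @param mix Named proportions over the archetypes (must sum to 1 within
#'   1e-9). See [default_mix()] for the archetype names.
#' @param start,end Date range of the simulated record (defaults span a
#'   27-month observation window).
#' @param seed Integer master seed; all randomness derives from it.
#' @param mean_encounters Mean number of background (non-qualifying)
#'   encounters per patient (Poisson; default 6.6, a typical outpatient
#'   encounter count for this kind of cohort).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients, mix = default_mix(),
                        start = as.Date("2009-01-01"),
                        end = as.Date("2011-04-01"),
                        seed = 1L, mean_encounters = 6.6) {
  if (n_patients <= 0) abort("n_patients must be > 0")
  if (is.null(names(mix)) || !all(names(mix) %in% .archetypes)) {
    abort(sprintf("mix names must be archetypes: %s",
                  paste(.archetypes, collapse = ", ")))
  }
  if (abs(sum(mix) - 1) > 1e-9) abort("mix proportions must sum to 1")
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start + 400) abort("date range must span at least 400 days")
  structure(list(n_patients = as.integer(n_patients), mix = mix,
                 start = start, end = end, seed = as.integer(seed),
                 mean_encounters = mean_encounters),
            class = "cohort_spec")
}

# Deterministic per-patient substream: cohorts are stable in their first
# n patients when n grows. Kept below 2^31.
.patient_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 69621) %% 2147483647)
}

.rdate <- function(n, start, end) {
  start + floor(runif(n, 0, as.numeric(end - start) + 1))
}

# Background (never-qualifying) events: distractor encounters and normal
# labs. Values sit safely below every diagnostic threshold.
.background_events <- function(pid, n, start, end) {
  if (n <= 0L) return(empty_events())
  dates <- .rdate(n, start, end)
  kinds <- sample(c("enc", "hba1c", "fbg", "med"), n, replace = TRUE,
                  prob = c(0.55, 0.15, 0.2, 0.1))
  rows <- lapply(seq_len(n), function(i) {
    switch(kinds[i],
      enc = encounter_event(pid, dates[i],
                            sample(.distractor_codes, 1),
                            sample(c("outpatient", "inpatient",
                                     "emergency_urgent"), 1,
                                   prob = c(0.8, 0.1, 0.1))),
      hba1c = lab_event(pid, dates[i], "hba1c",
                        round(runif(1, 5.0, 5.6), 1)),
      fbg = lab_event(pid, dates[i], "fasting_glucose",
                      round(runif(1, 80, 99))),
      med = medication_event(pid, dates[i], "non_diabetes_medication"))
  })
  dplyr::bind_rows(rows)
}

.diabetic_hba1c <- function(n = 1) {
  pmin(round(exp(rnorm(n, log(8.0), 0.12)), 1), 14)
}
.diabetic_fbg <- function(n = 1) {
  pmax(round(exp(rnorm(n, log(165), 0.15))), 126)
}

# One synthetic patient. Returns list(patient, events, gold_category,
# gold_date). gold_date is the earliest date the constructed chart
# satisfies the archetype's diagnostic evidence.
.generate_patient <- function(pid, archetype, start, end, mean_encounters) {
  min_age <- if (archetype == "healthy_elderly") 50 else 18
  age <- runif(1, min_age, 90)
  birth <- start - round(age * 365.25)
  sex <- sample(c("male", "female"), 1)
  if (archetype == "pcos_metformin") sex <- "female"
  payer <- sample(.payers, 1, prob = c(0.16, 0.06, 0.13, 0.29, 0.32, 0.04))

  span <- as.numeric(end - start)
  d1 <- start + floor(runif(1, 0, span - 240))
  gap <- floor(runif(1, 30, 181))
  d2 <- d1 + gap

  gold_category <- "none"
  gold_date <- as.Date(NA)
  core <- empty_events()

  if (archetype == "true_diabetic_labs") {
    # Two outpatient fasting glucoses >= 126 on distinct dates; second
    # crosses the threshold. Deliberately no 250.xx encounter codes.
    core <- rbind(
      lab_event(pid, d1, "fasting_glucose", .diabetic_fbg()),
      lab_event(pid, d2, "fasting_glucose", .diabetic_fbg()))
    if (runif(1) < 0.5) {
      core <- rbind(core, lab_event(pid, d2 + floor(runif(1, 20, 120)),
                                    "hba1c", .diabetic_hba1c()))
    }
    gold_category <- "diabetes"; gold_date <- d2
  } else if (archetype == "true_diabetic_meds") {
    core <- medication_event(pid, d1, "other_diabetes_medication")
    if (runif(1) < 0.6) {
      core <- rbind(core, lab_event(pid, d1 + floor(runif(1, 0, 90)),
                                    "hba1c", .diabetic_hba1c()))
    }
    gold_category <- "diabetes"; gold_date <- d1
  } else if (archetype == "true_diabetic_codes") {
    # Repeat 250.xx encounters; the second distinct date crosses 1 point.
    code <- sample(c("250.00", "250.02", "250.60"), 1)
    core <- rbind(
      encounter_event(pid, d1, code,
                      sample(c("outpatient", "inpatient"), 1,
                             prob = c(0.85, 0.15))),
      encounter_event(pid, d2, code, "outpatient"))
    if (runif(1) < 0.4) {
      core <- rbind(core,
        encounter_event(pid, d2 + floor(runif(1, 30, 120)), code))
    }
    gold_category <- "diabetes"; gold_date <- d2
  } else if (archetype == "prediabetic_metformin") {
    # Metformin for pre-diabetes: borderline labs, no diabetes.
    core <- rbind(
      medication_event(pid, d1, "metformin"),
      lab_event(pid, d1, "hba1c", round(runif(1, 5.7, 6.4), 1)),
      lab_event(pid, d2, "fasting_glucose", round(runif(1, 100, 125))))
  } else if (archetype == "pcos_metformin") {
    # Metformin for polycystic ovarian syndrome: normal glycemia.
    core <- rbind(
      medication_event(pid, d1, "metformin"),
      encounter_event(pid, d1, "256.4"),
      lab_event(pid, d2, "hba1c", round(runif(1, 5.0, 5.6), 1)))
  } else if (archetype == "stale_problem_list") {
    # Inaccurate problem-list entry; the rest of the chart is clean.
    core <- rbind(
      history_event(pid, d1, "250.00",
                    sample(.history_sources, 1)),
      lab_event(pid, d2, "hba1c", round(runif(1, 5.0, 5.6), 1)))
  } else if (archetype == "miscoded_single_icd9") {
    # One isolated miscoded 250.xx encounter, never repeated.
    core <- rbind(
      encounter_event(pid, d1, "250.00"),
      lab_event(pid, d2, "fasting_glucose", round(runif(1, 80, 99))))
  }

  n_bg <- rpois(1, mean_encounters)
  events <- rbind(core, .background_events(pid, n_bg, start, end))

  list(
    patient = tibble::tibble(patient_id = pid, birth_date = birth,
                             sex = sex, payer = payer),
    events = events,
    gold = tibble::tibble(patient_id = pid, gold_category = gold_category,
                          gold_date = gold_date)
  )
}

#' Generate a synthetic EHR cohort with known ground truth
#'
#' Fully reproducible given the spec's seed: each patient's randomness is
#' drawn from a substream derived from `(seed, patient index)`, so the
#' first `n` patients are identical across runs and stable when
#' `n_patients` grows. Gold diagnosis dates are constructed as the earliest
#' date the generated chart satisfies the archetype's diagnostic evidence
#' (e.g. the second qualifying fasting glucose), so earliest-date recovery
#' by the scorer is exactly checkable.
#'
#' @param spec A [cohort_spec()].
#' @return List with `cohort` (an [ehr_cohort()]) and `gold` (a tibble of
#'   `patient_id, gold_category, gold_date`). Each patient's archetype is
#'   recorded in `gold$archetype`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  mix <- spec$mix[spec$mix > 0]
  patients <- vector("list", spec$n_patients)
  events <- vector("list", spec$n_patients)
  gold <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    set.seed(.patient_seed(spec$seed, i))
    arch <- sample(names(mix), 1, prob = mix)
    pid <- sprintf("P%06d", i)
    p <- .generate_patient(pid, arch, spec$start, spec$end,
                           spec$mean_encounters)
    p$gold$archetype <- arch
    patients[[i]] <- p$patient
    events[[i]] <- p$events
    gold[[i]] <- p$gold
  }
  list(
    cohort = ehr_cohort(dplyr::bind_rows(patients),
                        dplyr::bind_rows(events)),
    gold = dplyr::bind_rows(gold)
  )
}

#' Stratified sampling fractions used in model derivation and validation
#'
#' Presets for chart-review sampling by model category: the derivation
#' design (50% diabetes / 25% possible / 25% none) and the validation
#' design (50% / 10% / 40%).
#'
#' @param design `"derivation_50_25_25"` or `"validation_50_10_40"`.
#' @return Named proportions over `diabetes, possible, none`.
#' @export
sampling_fractions <- function(design = c("derivation_50_25_25",
                                          "validation_50_10_40")) {
  design <- match.arg(design)
  if (design == "derivation_50_25_25") {
    c(diabetes = 0.50, possible = 0.25, none = 0.25)
  } else {
    c(diabetes = 0.50, possible = 0.10, none = 0.40)
  }
}

#' Stratified random sample of patients by model category
#'
#' Samples up to `n` patients without replacement, split across the model's
#' three categories by the given fractions. A stratum smaller than its
#' quota contributes all its members, with a warning (the sample is then
#' "up to" `n`).
#'
#' @param scores Tibble from [score_cohort()].
#' @param fractions Named proportions over `diabetes, possible, none`
#'   summing to 1; see [sampling_fractions()].
#' @param n Target total sample size.
#' @param seed Integer seed.
#' @return Character vector of sampled `patient_id`s.
#' @export
stratified_sample <- function(scores, fractions, n, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) abort("fractions must sum to 1")
  if (!all(names(fractions) %in% .categories)) {
    abort("fractions must be named by category (none/possible/diabetes)")
  }
  if (n == 0L) return(character())
  quotas <- round(n * fractions)
  set.seed(seed)
  out <- character()
  for (cat in names(fractions)) {
    pool <- scores$patient_id[scores$category == cat]
    q <- quotas[[cat]]
    if (length(pool) < q) {
      warn(sprintf(
        "stratum '%s' has only %d patient(s) for a quota of %d; taking all",
        cat, length(pool), q))
      take <- pool
    } else {
      take <- sample(pool, q)
    }
    out <- c(out, take)
  }
  out
}

#' Age-restrict one category stratum of a cohort
#'
#' Removes from the cohort the patients of a given model category younger
#' than `min_age_years` at their first encounter; other strata are
#' untouched. Used to enrich the negative stratum with older patients, in
#' whom missed diabetes is more likely, when assembling review samples.
#'
#' @param cohort An `ehr_cohort` with birth dates.
#' @param categories Tibble with `patient_id` and `category` (e.g. the
#'   output of [score_cohort()]).
#' @param min_age_years Minimum age in completed years (inclusive;
#'   default 50).
#' @param stratum Category to restrict (default `"none"`).
#' @return A filtered `ehr_cohort`.
#' @export
age_restrict <- function(cohort, categories, min_age_years = 50,
                         stratum = "none") {
  stopifnot(inherits(cohort, "ehr_cohort"))
  first_enc <- cohort$events |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first = min(.data$date), .groups = "drop")
  info <- cohort$patients |>
    dplyr::left_join(first_enc, by = "patient_id") |>
    dplyr::left_join(categories[, c("patient_id", "category")],
                     by = "patient_id")
  age <- floor(as.numeric(info$first - info$birth_date) / 365.25)
  drop <- !is.na(info$category) & info$category == stratum &
    !is.na(age) & age < min_age_years
  keep_ids <- info$patient_id[!drop]
  ehr_cohort(
    cohort$patients[cohort$patients$patient_id %in% keep_ids, ],
    cohort$events[cohort$events$patient_id %in% keep_ids, ]
  )
}
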