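# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: the kappa, AUC and diagnosis-date oracles are
# brute-force definitional computations.

# Brute-force earliest diagnosis date: score every prefix of events dated
# <= d for each distinct date d and return the first date whose prefix is
# classified diabetes. Independent of the streaming scorer's accrual walk
# only in how the date is found; it reuses scoring of static prefixes.
oracle_diagnosis_date <- function(timeline, config = default_config()) {
  dates <- sort(unique(timeline$date))
  for (d in as.list(dates)) {
    prefix <- timeline[timeline$date <= d, , drop = FALSE]
    if (score_patient(prefix, config)$category == "diabetes") return(d)
  }
  as.Date(NA)
}

# Definitional Cohen's kappa: explicit double loop over cells.
oracle_kappa <- function(tab, linear = FALSE) {
  tab <- as.matrix(tab)
  k <- nrow(tab)
  n <- sum(tab)
  po <- 0; pe <- 0
  rs <- rowSums(tab); cs <- colSums(tab)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- if (linear) 1 - abs(i - j) / (k - 1) else as.numeric(i == j)
      po <- po + w * tab[i, j] / n
      pe <- pe + w * (rs[i] / n) * (cs[j] / n)
    }
  }
  unname((po - pe) / (1 - pe))
}

# Tie-corrected Mann-Whitney probability: P(pos > neg) + 0.5 P(pos == neg)
# by explicit pair counting.
oracle_auc_mw <- function(totals, positive) {
  pos <- totals[positive]; neg <- totals[!positive]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# Random small timeline over all event kinds, settings and boundary lab
# values, for property tests.
random_timeline <- function(pid, n_events,
                            start = as.Date("2009-01-01"), span = 400) {
  dates <- start + sample.int(span, n_events, replace = TRUE)
  rows <- lapply(seq_len(n_events), function(i) {
    setting <- sample(c("outpatient", "inpatient", "emergency_urgent"), 1,
                      prob = c(0.6, 0.25, 0.15))
    switch(sample(c("enc", "lab", "med", "hist"), 1),
      enc = encounter_event(pid, dates[i],
        sample(c("250.00", "250.6", "250", "401.9", "2500"), 1), setting),
      lab = {
        kind <- sample(c("hba1c", "fasting_glucose", "random_glucose",
                         "ogtt_2h"), 1)
        value <- switch(kind,
          hba1c = sample(c(5.4, 6.4, 6.5, 8.1), 1),
          fasting_glucose = sample(c(90, 125, 126, 180), 1),
          sample(c(140, 199, 200, 320), 1))
        lab_event(pid, dates[i], kind, value, setting)
      },
      med = medication_event(pid, dates[i],
        sample(c("metformin", "other_diabetes_medication",
                 "non_diabetes_medication"), 1), setting),
      hist = history_event(pid, dates[i],
        sample(c("250.00", "428.0"), 1),
        sample(c("problem_list", "past_medical_history"), 1), setting))
  })
  dplyr::bind_rows(rows)
}

# Three canonical single-evidence patients: one diabetes, one possible,
# one none.
three_patient_cohort <- function() {
  ev <- rbind(
    lab_event("dm", "2009-03-01", "fasting_glucose", 130),
    lab_event("dm", "2009-05-01", "fasting_glucose", 126),
    medication_event("poss", "2009-02-10", "metformin"),
    medication_event("neg", "2009-02-10", "non_diabetes_medication"))
  ehr_cohort(events = ev)
}
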