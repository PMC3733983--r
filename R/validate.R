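# Composite validation report: model output vs gold-standard labels.

#' Validate cohort scores against gold-standard labels
#'
#' Assembles the full validation report for a scored cohort: the 3x3
#' agreement table over `none/possible/diabetes`, Cohen's kappa (unweighted
#' and linear-weighted), binary metrics under both dichotomisations of the
#' `"possible"` group, an ROC threshold sweep with its C statistic, and
#' diagnosis-date agreement (exact and within the window, both symmetric
#' and model-late readings, plus a quarter-bin date kappa labelled as a
#' reconstruction). If a claims-comparator table is supplied, its date
#' agreement against gold is reported alongside.
#'
#' Predictive values are computed on the supplied cohort as-is; when the
#' cohort was assembled by enriched (stratified) sampling, PPV and NPV are
#' inflated relative to the source population and should be read
#' accordingly.
#'
#' @param scores Tibble from [score_cohort()].
#' @param gold Tibble from [read_gold()] (or equivalent), matching
#'   `scores$patient_id` one-to-one.
#' @param claims Optional tibble from [claims_cohort()].
#' @param window_days Date-agreement window in days (default 92).
#' @param thresholds Optional ROC threshold grid.
#' @return A list of class `validation_report`.
#' @export
validate_scores <- function(scores, gold, claims = NULL, window_days = 92L,
                            thresholds = NULL) {
  unmatched <- c(setdiff(scores$patient_id, gold$patient_id),
                 setdiff(gold$patient_id, scores$patient_id))
  if (length(unmatched) > 0L) {
    abort(sprintf("patient ids do not align; offenders: %s",
                  paste(head(sort(unique(unmatched)), 10L), collapse = ", ")))
  }
  if (anyDuplicated(scores$patient_id) || anyDuplicated(gold$patient_id)) {
    abort("patient ids must be unique in scores and gold")
  }
  gold <- gold[match(scores$patient_id, gold$patient_id), ]

  tab <- agreement_table(scores$category, gold$gold_category)

  both_modes <- lapply(
    c(possible_as_negative = "possible_as_negative",
      possible_as_positive = "possible_as_positive"),
    function(mode) {
      pred <- collapse_labels(scores$category, mode)
      truth <- collapse_labels(gold$gold_category, mode)
      cm <- .confusion2(pred, truth)
      c(cm, binary_metrics(cm$tp, cm$fp, cm$fn, cm$tn))
    })

  gold_pos <- collapse_labels(gold$gold_category, "possible_as_negative")
  roc <- if (any(gold_pos) && !all(gold_pos)) {
    roc_over_thresholds(scores$total_points, gold_pos, thresholds)
  } else NULL

  dates_model <- date_agreement(scores$diagnosis_date, gold$gold_date,
                                window_days, "symmetric")
  dates_model_late <- date_agreement(scores$diagnosis_date, gold$gold_date,
                                     window_days, "model_late")

  dates_claims <- NULL
  if (!is.null(claims)) {
    cl <- claims[match(scores$patient_id, claims$patient_id), ]
    dates_claims <- date_agreement(cl$diagnosis_date, gold$gold_date,
                                   window_days, "symmetric")
  }

  date_detail <- tibble::tibble(
    patient_id = scores$patient_id,
    model_date = scores$diagnosis_date,
    gold_date = gold$gold_date,
    delay_days = as.integer(scores$diagnosis_date - gold$gold_date),
    within_window = !is.na(scores$diagnosis_date) & !is.na(gold$gold_date) &
      abs(as.integer(scores$diagnosis_date - gold$gold_date)) <= window_days
  )

  structure(list(
    n = nrow(scores),
    agreement_table = tab,
    kappa_unweighted = cohen_kappa(tab, "unweighted"),
    kappa_linear = cohen_kappa(tab, "linear"),
    binary = both_modes,
    roc = roc,
    date_agreement = dates_model,
    date_agreement_model_late = dates_model_late,
    date_kappa_quarter = .quarter_kappa(scores$diagnosis_date,
                                        gold$gold_date),
    date_agreement_claims = dates_claims,
    date_detail = date_detail,
    window_days = as.integer(window_days)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n = %d\n", x$n))
  cat(sprintf("  kappa: %.3f unweighted, %.3f linear-weighted\n",
              x$kappa_unweighted, x$kappa_linear))
  b <- x$binary$possible_as_negative
  cat(sprintf(
    "  possible->negative: sens %.3f, spec %.3f, PPV %.3f, NPV %.3f\n",
    b$sensitivity, b$specificity, b$ppv, b$npv))
  b <- x$binary$possible_as_positive
  cat(sprintf("  possible->positive: sens %.3f, spec %.3f\n",
              b$sensitivity, b$specificity))
  if (!is.null(x$roc)) {
    cat(sprintf("  C statistic: %.3f over %d threshold(s)\n",
                x$roc$auc, nrow(x$roc$points)))
  }
  d <- x$date_agreement
  if (d$n_pairs > 0L) {
    cat(sprintf(
      "  dates: %d/%d exact (%.1f%%), %d/%d within %d days (%.1f%%)\n",
      d$n_exact, d$n_pairs, 100 * d$n_exact / d$n_pairs,
      d$n_within_window, d$n_pairs, d$window_days,
      100 * d$n_within_window / d$n_pairs))
  }
  invisible(x)
}

# Flatten a date_agreement for JSON.
.da_json <- function(d) {
  if (is.null(d)) return(NULL)
  list(n_pairs = d$n_pairs, n_exact = d$n_exact,
       n_within_window = d$n_within_window, window_days = d$window_days,
       sided = d$sided,
       prop_exact = if (d$n_pairs > 0) d$n_exact / d$n_pairs else NA,
       prop_within = if (d$n_pairs > 0) d$n_within_window / d$n_pairs
                     else NA)
}

#' Write a validation report and its companion tables
#'
#' Writes `validation_report.json` (nested statistics), `roc.csv`
#' (`threshold, sensitivity, specificity`) and `dates.csv` (`patient_id,
#' model_date, gold_date, delay_days, within_window`) into a directory.
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- list(
    n = report$n,
    agreement_table = as.data.frame.matrix(
      unclass(report$agreement_table)),
    kappa_unweighted = report$kappa_unweighted,
    kappa_linear = report$kappa_linear,
    binary = report$binary,
    auc = if (!is.null(report$roc)) report$roc$auc else NULL,
    date_agreement = .da_json(report$date_agreement),
    date_agreement_model_late = .da_json(report$date_agreement_model_late),
    date_kappa_quarter = report$date_kappa_quarter,
    date_agreement_claims = .da_json(report$date_agreement_claims),
    window_days = report$window_days
  )
  jsonlite::write_json(out, file.path(dir, "validation_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (!is.null(report$roc)) {
    readr::write_csv(report$roc$points, file.path(dir, "roc.csv"))
  }
  dd <- report$date_detail
  dd$model_date <- format(dd$model_date, "%Y-%m-%d")
  dd$gold_date <- format(dd$gold_date, "%Y-%m-%d")
  readr::write_csv(dd, file.path(dir, "dates.csv"), na = "")
  invisible(dir)
}
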