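# Scoring configuration: criteria, weights, setting masks, accrual policy.
# All point arithmetic is done in integer centipoints (1 point = 100) so the
# diagnostic threshold comparison is exact; every shipped weight is a
# multiple of 0.05.

.criterion_names <- c("icd9_encounter", "hba1c", "fasting_glucose",
                      "random_glucose", "ogtt_2h", "history_dx",
                      "diabetes_medication", "metformin")
.accrual_policies <- c("per_distinct_date", "once_per_patient")

.points_to_centi <- function(points) {
  centi <- round(points * 100)
  if (any(abs(points * 100 - centi) > 1e-6)) {
    abort("point values must be exact multiples of 0.01")
  }
  as.integer(centi)
}

#' Default scoring configuration (published model weights)
#'
#' Returns the shipped weight configuration of the point-based case-finding
#' model: eight criteria with their qualifying rules, care-setting
#' restrictions, point values, and accrual policies, plus the diagnostic
#' threshold of 1 point.
#'
#' The criteria are: an ICD-9 250.xx encounter diagnosis (0.75 points, any
#' setting, at most once per calendar date); HbA1c >= 6.5% (1.00, any
#' setting); fasting glucose >= 126 mg/dL and random glucose >= 200 mg/dL
#' (0.50 each, outpatient only); 2-hour OGTT >= 200 mg/dL (0.75, any
#' setting); a 250.xx problem-list or past-medical-history entry (0.40, once
#' per patient); a non-metformin diabetes medication (1.00, outpatient only,
#' once per patient); and metformin (0.75, outpatient only, once per
#' patient). Lab thresholds are inclusive (`>=`). "Outpatient only" excludes
#' both inpatient and emergency/urgent settings.
#'
#' @return A `weight_config` object: a list with a `criteria` tibble
#'   (columns `name, threshold, units, code_prefix, allowed_settings,
#'   weight, accrual`) and scalars `diabetes_threshold` (1.0) and
#'   `possible_lower` (0).
#' @export
default_config <- function() {
  criteria <- tibble::tribble(
    ~name,                 ~threshold, ~units,  ~code_prefix, ~allowed_settings,                ~weight, ~accrual,
    "icd9_encounter",      NA_real_,   NA,      "250",        list(c("inpatient", "outpatient")), 0.75,  "per_distinct_date",
    "hba1c",               6.5,        "%",     NA,           list(c("inpatient", "outpatient")), 1.00,  "per_distinct_date",
    "fasting_glucose",     126,        "mg/dL", NA,           list("outpatient"),                 0.50,  "per_distinct_date",
    "random_glucose",      200,        "mg/dL", NA,           list("outpatient"),                 0.50,  "per_distinct_date",
    "ogtt_2h",             200,        "mg/dL", NA,           list(c("inpatient", "outpatient")), 0.75,  "per_distinct_date",
    "history_dx",          NA_real_,   NA,      "250",        list(c("inpatient", "outpatient")), 0.40,  "once_per_patient",
    "diabetes_medication", NA_real_,   NA,      NA,           list("outpatient"),                 1.00,  "once_per_patient",
    "metformin",           NA_real_,   NA,      NA,           list("outpatient"),                 0.75,  "once_per_patient"
  )
  weight_config(criteria, diabetes_threshold = 1.0)
}

#' Construct a weight configuration
#'
#' @param criteria Tibble of criteria with columns `name, threshold, units,
#'   code_prefix, allowed_settings` (list column of character vectors),
#'   `weight, accrual`.
#' @param diabetes_threshold Point total at or above which the classifier
#'   outputs `"diabetes"`; must be positive.
#' @return A validated `weight_config` object.
#' @export
weight_config <- function(criteria, diabetes_threshold = 1.0) {
  stopifnot(is.data.frame(criteria))
  req <- c("name", "threshold", "units", "code_prefix", "allowed_settings",
           "weight", "accrual")
  missing <- setdiff(req, names(criteria))
  if (length(missing) > 0L) {
    abort(sprintf("criteria table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(criteria$name)) abort("criterion names must be unique")
  if (!all(criteria$name %in% .criterion_names)) {
    abort(sprintf("unknown criterion name(s): %s",
      paste(setdiff(criteria$name, .criterion_names), collapse = ", ")))
  }
  if (!all(criteria$accrual %in% .accrual_policies)) {
    abort("accrual must be 'per_distinct_date' or 'once_per_patient'")
  }
  if (any(criteria$weight < 0)) abort("criterion weights must be >= 0")
  criteria$allowed_settings <- lapply(criteria$allowed_settings,
                                      function(s) as.character(unlist(s)))
  if (any(!vapply(criteria$allowed_settings,
                  function(s) length(s) > 0L && all(s %in% .settings),
                  logical(1)))) {
    abort("allowed_settings must be non-empty subsets of the care settings")
  }
  if (diabetes_threshold <= 0) abort("diabetes_threshold must be > 0")
  criteria$weight_centi <- .points_to_centi(criteria$weight)
  structure(list(
    criteria = tibble::as_tibble(criteria),
    diabetes_threshold = diabetes_threshold,
    threshold_centi = .points_to_centi(diabetes_threshold),
    possible_lower = 0
  ), class = "weight_config")
}

#' @export
print.weight_config <- function(x, ...) {
  cat(sprintf("<weight_config> %d criteria, diabetes threshold %.2f points\n",
              nrow(x$criteria), x$diabetes_threshold))
  df <- x$criteria
  df$allowed_settings <- vapply(df$allowed_settings, paste, character(1),
                                collapse = "+")
  print(df[, c("name", "threshold", "units", "code_prefix",
               "allowed_settings", "weight", "accrual")])
  invisible(x)
}

#' Look up a single criterion in a configuration
#'
#' @param config A `weight_config`.
#' @param name Criterion name.
#' @return One-row tibble for the criterion.
#' @export
get_criterion <- function(config, name) {
  stopifnot(inherits(config, "weight_config"))
  row <- config$criteria[config$criteria$name == name, , drop = FALSE]
  if (nrow(row) == 0L) abort(sprintf("no criterion named '%s'", name))
  row
}

#' Modify criterion weights in a configuration
#'
#' Returns a new configuration with selected criterion weights replaced;
#' used for site recalibration and for sensitivity analyses (e.g. restoring
#' the metformin weight to 1.0).
#'
#' @param config A `weight_config`.
#' @param ... Named point values, e.g. `metformin = 1.0`.
#' @return A new `weight_config`.
#' @export
set_weights <- function(config, ...) {
  stopifnot(inherits(config, "weight_config"))
  upd <- list(...)
  criteria <- config$criteria
  for (nm in names(upd)) {
    idx <- which(criteria$name == nm)
    if (length(idx) == 0L) abort(sprintf("no criterion named '%s'", nm))
    criteria$weight[idx] <- upd[[nm]]
  }
  weight_config(criteria[, setdiff(names(criteria), "weight_centi")],
                diabetes_threshold = config$diabetes_threshold)
}

#' Read a weight configuration from YAML or JSON
#'
#' The file holds `diabetes_threshold` and a `criteria` list; each criterion
#' has `name`, `weight`, `accrual`, `allowed_settings`, and either a lab
#' `threshold` (with `units`) or an ICD-9 `code_prefix`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `weight_config`.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) abort(sprintf("weights file not found: %s", path))
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(spec$criteria)) abort("weights file lacks a 'criteria' list")
  rows <- lapply(spec$criteria, function(cr) {
    tibble::tibble(
      name = cr$name,
      threshold = if (is.null(cr$threshold)) NA_real_ else as.numeric(cr$threshold),
      units = if (is.null(cr$units)) NA_character_ else cr$units,
      code_prefix = if (is.null(cr$code_prefix)) NA_character_ else cr$code_prefix,
      allowed_settings = list(unlist(cr$allowed_settings)),
      weight = as.numeric(cr$weight),
      accrual = cr$accrual
    )
  })
  weight_config(
    dplyr::bind_rows(rows),
    diabetes_threshold = if (is.null(spec$diabetes_threshold)) 1.0
                         else as.numeric(spec$diabetes_threshold)
  )
}

#' Write a weight configuration to YAML
#'
#' Inverse of [read_weights()].
#'
#' @param config A `weight_config`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_weights <- function(config, path) {
  stopifnot(inherits(config, "weight_config"))
  criteria <- lapply(seq_len(nrow(config$criteria)), function(i) {
    row <- config$criteria[i, ]
    out <- list(name = row$name, weight = row$weight, accrual = row$accrual,
                allowed_settings = row$allowed_settings[[1]])
    if (!is.na(row$threshold)) {
      out$threshold <- row$threshold
      out$units <- row$units
    }
    if (!is.na(row$code_prefix)) out$code_prefix <- row$code_prefix
    out
  })
  yaml::write_yaml(list(diabetes_threshold = config$diabetes_threshold,
                        criteria = criteria), path)
  invisible(path)
}
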