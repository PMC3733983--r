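# Agreement and discrimination statistics for validating case-finding
# output against gold-standard labels.

#' Binary classification metrics from a 2x2 confusion matrix
#'
#' Standard sensitivity, specificity, positive and negative predictive
#' value. A metric whose denominator is zero is reported as `NA`
#' (undefined), never as 0.
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return Named list with `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
binary_metrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  if (tp + fp + fn + tn == 0) abort("confusion matrix total must be > 0")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn)
  )
}

#' Collapse three-way labels to a dichotomy
#'
#' The three-way output is dichotomised two ways for binary metrics: with
#' the `"possible"` group combined with the negatives
#' (`possible_as_negative`, the primary analysis) or with the positives
#' (`possible_as_positive`, the alternate grouping).
#'
#' @param labels Character vector over `none/possible/diabetes`.
#' @param mode `"possible_as_negative"` or `"possible_as_positive"`.
#' @return Logical vector: `TRUE` = positive for diabetes.
#' @export
collapse_labels <- function(labels,
                            mode = c("possible_as_negative",
                                     "possible_as_positive")) {
  mode <- match.arg(mode)
  bad <- !labels %in% .categories
  if (any(bad)) {
    abort(sprintf("unknown label(s): %s",
                  paste(unique(labels[bad]), collapse = ", ")))
  }
  if (mode == "possible_as_negative") labels == "diabetes"
  else labels %in% c("possible", "diabetes")
}

# 2x2 confusion counts from logical prediction/truth vectors.
.confusion2 <- function(pred, truth) {
  list(tp = sum(pred & truth), fp = sum(pred & !truth),
       fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' Cohen's kappa (unweighted or linear-weighted)
#'
#' Chance-corrected agreement between two categorical labelings over the
#' same ordered categories. With `weights = "linear"`, agreement weights
#' are `w_ij = 1 - |i - j| / (k - 1)` so near-misses on the ordered scale
#' receive partial credit; on a 2x2 table the linear and unweighted
#' statistics coincide. If expected agreement is exactly 1 (degenerate
#' marginals) the statistic is undefined and `NA` is returned.
#'
#' @param table Square contingency matrix (rows = rater 1, cols = rater 2,
#'   same ordered categories in the same order).
#' @param weights `"unweighted"` or `"linear"`.
#' @return Kappa statistic in `[-1, 1]`, or `NA` if undefined.
#' @export
cohen_kappa <- function(table, weights = c("unweighted", "linear")) {
  weights <- match.arg(weights)
  table <- as.matrix(table)
  if (nrow(table) != ncol(table)) abort("agreement table must be square")
  if (any(table < 0)) abort("agreement table entries must be >= 0")
  n <- sum(table)
  if (n == 0) abort("agreement table total must be > 0")
  k <- nrow(table)
  w <- if (weights == "unweighted" || k == 1L) {
    diag(k)
  } else {
    1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  }
  p <- table / n
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  if (isTRUE(all.equal(pe, 1))) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Build a 3x3 agreement table from model and gold categories
#'
#' @param model,gold Character vectors over `none/possible/diabetes`,
#'   aligned by position.
#' @return 3x3 contingency matrix (rows = model, cols = gold) in category
#'   order `none, possible, diabetes`.
#' @export
agreement_table <- function(model, gold) {
  stopifnot(length(model) == length(gold))
  table(factor(model, levels = .categories),
        factor(gold, levels = .categories))
}

#' ROC curve over point thresholds
#'
#' Sweeps a threshold grid over patient point totals: at each threshold `t`
#' a patient is predicted positive iff `total >= t`, and sensitivity /
#' specificity are computed against the binary gold label. The AUC
#' (C statistic) is the trapezoidal area over the `(1 - specificity,
#' sensitivity)` points augmented with (0,0) and (1,1).
#'
#' @param totals Numeric point totals, one per patient.
#' @param gold_positive Logical gold labels aligned with `totals`.
#' @param thresholds Threshold grid; defaults to the sorted distinct
#'   observed totals.
#' @return A list of class `roc_curve`: `points` tibble (`threshold,
#'   sensitivity, specificity`) and scalar `auc`.
#' @export
roc_over_thresholds <- function(totals, gold_positive, thresholds = NULL) {
  stopifnot(length(totals) == length(gold_positive))
  if (!any(gold_positive) || all(gold_positive)) {
    abort("gold labels must include at least one positive and one negative")
  }
  if (is.null(thresholds)) thresholds <- sort(unique(totals))
  thresholds <- sort(unique(thresholds))
  pts <- lapply(thresholds, function(t) {
    cm <- .confusion2(totals >= t, gold_positive)
    m <- binary_metrics(cm$tp, cm$fp, cm$fn, cm$tn)
    tibble::tibble(threshold = t, sensitivity = m$sensitivity,
                   specificity = m$specificity)
  })
  pts <- dplyr::bind_rows(pts)
  fpr <- c(0, rev(1 - pts$specificity), 1)
  tpr <- c(0, rev(pts$sensitivity), 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d threshold(s), AUC (C statistic) %.3f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Diagnosis-date agreement
#'
#' Compares model-determined diagnosis dates against gold-standard dates
#' for patients diagnosed by both. A pair agrees exactly when the dates are
#' equal, and agrees within the window when the signed delay
#' `model - gold` (days) lies inside it: symmetric mode requires
#' `|delay| <= window_days`; one-sided (`"model_late"`) mode requires
#' `0 <= delay <= window_days`, i.e. the model may only lag the gold date.
#' The default window of 92 days covers the longest 3-calendar-month span.
#'
#' @param model_date,gold_date Aligned `Date` vectors; pairs with either
#'   date missing are dropped before counting.
#' @param window_days Window half-width in days (default 92).
#' @param sided `"symmetric"` or `"model_late"`.
#' @return A list of class `date_agreement`: `n_pairs`, `n_exact`,
#'   `n_within_window`, `window_days`, `sided`, and `delays` (signed days,
#'   model minus gold).
#' @export
date_agreement <- function(model_date, gold_date, window_days = 92L,
                           sided = c("symmetric", "model_late")) {
  sided <- match.arg(sided)
  stopifnot(length(model_date) == length(gold_date), window_days >= 0)
  keep <- !is.na(model_date) & !is.na(gold_date)
  delays <- as.integer(model_date[keep] - gold_date[keep])
  within <- if (sided == "symmetric") abs(delays) <= window_days
            else delays >= 0L & delays <= window_days
  structure(list(
    n_pairs = length(delays),
    n_exact = sum(delays == 0L),
    n_within_window = sum(within),
    window_days = as.integer(window_days),
    sided = sided,
    delays = delays
  ), class = "date_agreement")
}

#' @export
print.date_agreement <- function(x, ...) {
  cat(sprintf(
    "<date_agreement> %d pair(s): %d exact, %d within %d days (%s)\n",
    x$n_pairs, x$n_exact, x$n_within_window, x$window_days, x$sided))
  invisible(x)
}

# Quarter-bin kappa on diagnosis dates: an agreement reconstruction, not a
# published definition. Dates are binned to calendar year-quarters and
# Cohen's kappa is computed on the two binnings over their union of
# occupied quarters.
.quarter_kappa <- function(model_date, gold_date) {
  keep <- !is.na(model_date) & !is.na(gold_date)
  if (sum(keep) == 0L) return(NA_real_)
  qb <- function(d) paste0(format(d, "%Y"), "Q",
                           (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L)
  m <- qb(model_date[keep]); g <- qb(gold_date[keep])
  lev <- sort(unique(c(m, g)))
  if (length(lev) == 1L) return(NA_real_)
  cohen_kappa(table(factor(m, lev), factor(g, lev)), "unweighted")
}
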